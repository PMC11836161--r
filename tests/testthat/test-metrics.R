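test_that("dice handles the edge conventions and the hand-count case", {
  d <- c(4, 4, 4)
  a <- array(FALSE, d); b <- array(FALSE, d)
  expect_equal(dice(a, b), 1)          # both empty
  a[1:8] <- TRUE
  expect_equal(dice(a, b), 0)          # one empty
  b[5:12] <- TRUE                      # |a|=8, |b|=8, overlap 4
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "mismatched")
})

test_that("assd matches hand geometry and spacing scales linearly", {
  d <- c(9, 9, 3)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[2, 2, 2] <- TRUE
  b[2, 5, 2] <- TRUE                   # 3 voxels apart along axis 2
  expect_equal(assd(a, b, c(1, 1, 1)), 3)
  expect_equal(assd(a, b, c(1, 2, 1)), 6)
  expect_equal(assd(a, a, c(1, 1, 1)), 0)
  expect_true(is.na(assd(a, array(FALSE, d), c(1, 1, 1))))
})

test_that("dice/iou/assd agree with brute-force oracles on random masks", {
  set.seed(2024)
  for (rep in 1:40) {
    dm <- sample(4:12, 3, replace = TRUE)
    a <- random_blob_mask(dm, p = runif(1, 0.1, 0.5))
    b <- random_blob_mask(dm, p = runif(1, 0.1, 0.5))
    sp <- runif(3, 0.4, 3.5)
    expect_equal(dice(a, b), brute_dice(a, b), tolerance = 1e-12)
    expect_equal(iou(a, b), brute_iou(a, b), tolerance = 1e-12)
    if (any(a) && any(b))
      expect_equal(assd(a, b, sp), brute_assd(a, b, sp), tolerance = 1e-9)
  }
})

test_that("instance matching honours the IoU >= 0.5 boundary", {
  d <- c(4, 20, 4)
  pred <- array(0L, d); ref <- array(0L, d)
  # engineered IoU exactly 0.5: |pred|=2, |ref|=4, overlap 2 -> 2/4
  ref[1, 1:4, 1] <- 1L
  pred[1, 1:2, 1] <- 7L
  mt <- match_instances(pred, ref, 0.5)
  expect_equal(nrow(mt$matches), 1)
  expect_equal(mt$matches$iou, 0.5)
  expect_length(mt$fp, 0); expect_length(mt$fn, 0)
  # nudge below the threshold: overlap 2 of union 5 -> 0.4
  ref[1, 5, 1] <- 1L
  mt2 <- match_instances(pred, ref, 0.5)
  expect_equal(nrow(mt2$matches), 0)
  expect_identical(mt2$fp, 7L)
  expect_identical(mt2$fn, 1L)
})

test_that("matching is greedy, one-to-one and relabel-invariant", {
  d <- c(6, 30, 4)
  pred <- array(0L, d); ref <- array(0L, d)
  ref[2:5, 2:9, 2:3] <- 1L; ref[2:5, 12:19, 2:3] <- 2L; ref[2:5, 22:29, 2:3] <- 3L
  pred[2:5, 2:8, 2:3] <- 10L            # overlaps ref 1 well
  pred[1, 1, 1] <- 20L                  # spurious
  mt <- match_instances(pred, ref)
  expect_equal(nrow(mt$matches), 1)
  expect_equal(mt$matches$pred, 10)
  expect_equal(mt$matches$ref, 1)
  expect_identical(mt$fp, 20L)
  expect_identical(sort(mt$fn), c(2L, 3L))
  # permuting ids changes no score
  perm_pred <- pred; perm_pred[pred == 10L] <- 77L; perm_pred[pred == 20L] <- 5L
  mt_p <- match_instances(perm_pred, ref)
  expect_equal(mt_p$matches$iou, mt$matches$iou)
  expect_equal(panoptic_scores(mt_p), panoptic_scores(mt))
  # identical masks match everything at IoU 1
  mt_id <- match_instances(ref, ref)
  expect_equal(nrow(mt_id$matches), 3)
  expect_true(all(mt_id$matches$iou == 1))
})

test_that("panoptic scores satisfy their identities", {
  d <- c(6, 30, 4)
  pred <- array(0L, d); ref <- array(0L, d)
  ref[2:5, 2:9, 2:3] <- 1L; ref[2:5, 12:19, 2:3] <- 2L; ref[2:5, 22:29, 2:3] <- 3L
  pred[2:5, 2:8, 2:3] <- 1L; pred[1, 1, 1] <- 9L
  # TP=1, FP=1, FN=2 -> RQ = 1/2.5
  sc <- panoptic_scores(match_instances(pred, ref))
  expect_equal(unname(sc["rq"]), 0.4)
  expect_equal(unname(sc["pq"]), unname(sc["rq"] * sc["sq"]))
  # synthetic match tables: PQ = RQ*SQ, all within [0,1]
  set.seed(99)
  for (rep in 1:100) {
    tp <- sample(0:6, 1); fp <- sample(0:4, 1); fn <- sample(0:4, 1)
    if (tp + fp + fn == 0) fn <- 1
    tbl <- structure(list(
      matches = data.frame(pred = seq_len(tp), ref = seq_len(tp),
                           iou = runif(tp, 0.5, 1)),
      fp = seq_len(fp) + 100, fn = seq_len(fn) + 200,
      iou_threshold = 0.5), class = "match_table")
    sc <- panoptic_scores(tbl)
    expect_equal(unname(sc["pq"]), unname(sc["rq"] * sc["sq"]))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_lte(sc["pq"], min(sc["rq"], sc["sq"]) + 1e-12)
  }
  empty <- structure(list(matches = data.frame(pred = integer(),
                                               ref = integer(),
                                               iou = numeric()),
                          fp = integer(), fn = integer(),
                          iou_threshold = 0.5), class = "match_table")
  expect_true(all(is.na(panoptic_scores(empty))))
})

test_that("instance masks collapse to anatomic-group masks", {
  ph <- small_phantom(3)
  grp <- derive_semantic_from_instances(ph$instances)
  expect_identical(which(grp$data == 1L),
                   which(ph$instances$data > 0 & ph$instances$data < 100))
  expect_identical(which(grp$data == 2L),
                   which(ph$instances$data >= 100 & ph$instances$data < 200))
  expect_identical(sort(unique(as.vector(grp$data))), c(0L, 1L, 2L, 3L))
  bad <- array(500L, c(2, 2, 2))
  expect_error(derive_semantic_from_instances(bad), "outside")
  empty <- array(0L, c(2, 2, 2))
  expect_true(all(derive_semantic_from_instances(empty) == 0L))
})

test_that("evaluate_subject is exact on identity and on a dropped vertebra", {
  ph <- small_phantom(5)
  ref <- mask_pair(ph$semantic, ph$instances)
  rep_id <- evaluate_subject(ref, ref)
  expect_true(all(rep_id$structures$dsc == 1))
  expect_true(all(rep_id$structures$assd == 0))
  expect_true(all(rep_id$instances[, c("dsc", "rq", "sq", "pq")] == 1))
  expect_true(all(rep_id$instances$assd == 0))
  # a prediction missing one whole vertebra: RQ = (N-1)/((N-1)+0.5)
  pred <- mask_pair(ph$semantic, ph$instances)
  pred$instances$data[pred$instances$data == 3L] <- 0L
  rep_m <- evaluate_subject(pred, ref)
  vr <- rep_m$instances[rep_m$instances$name == "vertebra", ]
  expect_equal(vr$rq, 4 / 4.5)
  expect_equal(vr$tp, 4); expect_equal(vr$fn, 1)
})

test_that("the signed-rank comparison behaves across regimes", {
  expect_equal(paired_signed_rank(rep(1, 10), rep(1, 10))$p_value, 1)
  a <- seq(0.5, 0.9, length.out = 20)
  shifted <- paired_signed_rank(a + 0.05, a)
  expect_lt(shifted$p_value, 0.05)
  expect_true(shifted$significant)
  set.seed(7)
  noise <- rnorm(20, 0, 0.01)
  same <- paired_signed_rank(a + noise, a + sample(noise))
  expect_gt(same$p_value, 0.05)
  expect_error(paired_signed_rank(1:3, 4:6), "at least 5")
  expect_error(paired_signed_rank(1:5, 1:6), "equal length")
})
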