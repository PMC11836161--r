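test_that("corpus centers are found, ordered top to bottom", {
  ph <- small_phantom(5)
  cen <- find_corpus_centers(ph$semantic)
  expect_equal(nrow(cen), 5)
  expect_identical(cen$rank, 1:5)
  expect_true(all(diff(cen$i) > 0))
  # ranks match ground-truth instance centroids
  gt_i <- vapply(1:5, function(v)
    mean(arrayInd(which(ph$instances$data == v &
                          ph$semantic$data == scheme_code("corpus")),
                  vol_dim(ph$semantic))[, 2]), numeric(1))
  expect_equal(cen$com_i, gt_i, tolerance = 1e-9)

  empty <- toy_volume()
  expect_equal(nrow(find_corpus_centers(empty)), 0)

  fused <- small_phantom(5, fused_pairs = list(c(2, 3)))
  expect_equal(nrow(find_corpus_centers(fused$semantic)), 4)
})

test_that("cutouts have the configured fixed size with background padding", {
  ph <- small_phantom(3)
  cen <- find_corpus_centers(ph$semantic)
  co <- extract_cutout(ph$semantic, cen[1, ], cutout_config())
  expect_identical(dim(co$data), c(248L, 304L, 64L))
  # topmost center: the superior part of the window is padded background
  expect_true(all(co$data[, 1:20, ] == 0L))
  # labels are a subset of the scheme
  expect_true(all(unique(as.vector(co$data)) %in% c(0L, 1:14)))
  expect_error(extract_cutout(ph$semantic, list(p = -3, i = 1, r = 1),
                              cutout_config()), "outside")
})

test_that("the placement transform round-trips voxels within one voxel", {
  ph <- small_phantom(3)
  cen <- find_corpus_centers(ph$semantic)
  co <- extract_cutout(ph$semantic, cen[2, ], cutout_config())
  pl <- co$placement
  # forward-map a canonical marker into the cutout grid, then invert
  marker <- c(cen$p[2] + 4, cen$i[2] - 3, cen$r[2])
  j <- round((marker - pl$center) / pl$ratio) + pl$c0
  u <- pl$center + (j - pl$c0) * pl$ratio
  expect_true(all(abs(u - marker) <= pmax(pl$ratio, 1)))
})

test_that("oracle predictions carry the three relative classes correctly", {
  ph <- small_phantom(4)
  cen <- find_corpus_centers(ph$semantic)
  cfg <- phantom_cutout_config(ph)
  pred <- oracle_cutout_predictor(ph)
  for (k in c(1, 2, 4)) {
    co <- extract_cutout(ph$semantic, cen[k, ], cfg)
    p <- predict_cutout(co, pred)
    gt <- spinemask:::.sample_canonical(ph$instances$data, co$placement)
    expect_identical(which(p$rel == 2L), which(gt == k))
    if (k > 1) expect_identical(which(p$rel == 1L), which(gt == k - 1))
    else expect_equal(sum(p$rel == 1L), 0)  # topmost: nothing above
    if (k < 4) expect_identical(which(p$rel == 3L), which(gt == k + 1))
    else expect_equal(sum(p$rel == 3L), 0)
  }
})

test_that("predictor contract violations are rejected", {
  ph <- small_phantom(3)
  cen <- find_corpus_centers(ph$semantic)
  cfg <- phantom_cutout_config(ph)
  co <- extract_cutout(ph$semantic, cen[1, ], cfg)
  bad_labels <- function(cutout) {
    r <- array(0L, dim(cutout$data)); r[1] <- 9L; r
  }
  expect_error(predict_cutout(co, bad_labels), "contract violation")
  bad_shape <- function(cutout) array(0L, c(2, 2, 2))
  expect_error(predict_cutout(co, bad_shape), "shape")
  # image-valued cutouts (intensities, not labels) violate the contract
  img_cutout <- co
  img_cutout$data <- array(runif(length(co$data)), dim(co$data))
  expect_error(predict_cutout(img_cutout, function(cutout)
    array(0L, dim(cutout$data))), "intensities")
})

test_that("appearance counts follow the two/three pattern", {
  for (n in c(3, 5, 7)) {
    ph <- small_phantom(n)
    cfg <- phantom_cutout_config(ph)
    cen <- find_corpus_centers(ph$semantic)
    preds <- lapply(seq_len(n), function(k)
      predict_cutout(extract_cutout(ph$semantic, cen[k, ], cfg),
                     oracle_cutout_predictor(ph)))
    sets <- collect_appearances(preds, cen)
    counts <- vapply(sets, function(s) length(s$idx), integer(1))
    expect_identical(counts, c(2L, rep(3L, n - 2), 2L))
    expect_true(all(vapply(sets, `[[`, numeric(1), "score") == 1))
  }
  # a lone vertebra yields a single appearance
  ph1 <- small_phantom(1)
  cen1 <- find_corpus_centers(ph1$semantic)
  preds1 <- list(predict_cutout(
    extract_cutout(ph1$semantic, cen1[1, ], phantom_cutout_config(ph1)),
    oracle_cutout_predictor(ph1)))
  sets1 <- collect_appearances(preds1, cen1)
  expect_length(sets1[[1]]$idx, 1)
  expect_equal(sets1[[1]]$score, 0)
})

test_that("consistency score: identical 1, half-overlap 0.5, single 0", {
  expect_equal(consistency_score(list(roles = c("center", "below", "above"),
                                      idx = list(1:10, 1:10, 1:10))), 1)
  # two appearances, 8 voxels each, 4 shared: 2*4/16 = 0.5
  expect_equal(consistency_score(list(roles = c("center", "below"),
                                      idx = list(1:8, 5:12))), 0.5)
  expect_equal(consistency_score(list(roles = "center", idx = list(1:3))), 0)
  expect_error(consistency_score(list(roles = character(), idx = list())),
               "empty")
})

test_that("fusion never overwrites higher-scored instances", {
  sem <- toy_volume(c(4, 20, 3))
  sem$data[2, 2:9, 2] <- scheme_code("corpus")
  sem$data[2, 12:19, 2] <- scheme_code("corpus")
  lin <- function(i) 2 + (i - 1) * 4 + (2 - 1) * 4 * 20
  up <- lin(2:9)       # vertebra 1 voxels
  down <- lin(12:19)   # vertebra 2 voxels
  contested <- lin(8:9)
  sets <- list(
    list(vertebra = 1L, roles = c("center", "above"),
         idx = list(up, up), score = 1.0),
    # lower-scored vertebra 2 also claims two of vertebra 1's voxels
    list(vertebra = 2L, roles = c("center", "above"),
         idx = list(c(contested, down), c(contested, down)), score = 0.5))
  fused <- fuse_instances(sets, sem)
  expect_true(all(fused$data[up] == 1L))
  expect_true(all(fused$data[down] == 2L))
})

test_that("fusion majority-votes appearances with center-role tie-break", {
  sem <- toy_volume(c(3, 10, 3))
  a <- 1:5; b <- 3:8; ctr <- c(1:5, 9L)
  sets <- list(list(vertebra = 1L, roles = c("below", "center", "above"),
                    idx = list(a, ctr, b), score = 0.5))
  fused <- fuse_instances(sets, sem)
  got <- which(fused$data == 1L)
  # majority (>= 2 of 3) keeps 1..5; voxels seen once (6..9) are dropped
  expect_identical(got, 1:5)
  # with two appearances, a tie falls to the center-role member
  sets2 <- list(list(vertebra = 1L, roles = c("center", "above"),
                     idx = list(c(1:4, 9L), 3:6), score = 0.5))
  got2 <- which(fuse_instances(sets2, sem)$data == 1L)
  expect_identical(got2, c(1L, 2L, 3L, 4L, 9L))
})

test_that("fused ids are renumbered consecutively from the top", {
  ph <- small_phantom(4)
  res <- segment_instances(ph$semantic, oracle_cutout_predictor(ph),
                           phantom_cutout_config(ph))
  inst <- res$instances$data
  verts <- sort(unique(inst[inst > 0 & inst < 100]))
  expect_identical(verts, 1:4)
  # vertebra and disc id ranges never collide
  expect_true(all(inst %in% c(0:99, 100:199, 200:299)))
})

test_that("disc and endplate components inherit the vertebra above", {
  ph <- small_phantom(4)
  res <- segment_instances(ph$semantic, oracle_cutout_predictor(ph),
                           phantom_cutout_config(ph))
  inst <- res$instances$data
  sem <- ph$semantic$data
  # disc between vertebrae 2 and 3 owns id derived from vertebra 2
  expect_identical(sort(unique(inst[sem == scheme_code("ivd")])),
                   ivd_instance_id(1:3))
  expect_identical(inst[ph$instances$data == ivd_instance_id(2L)][1],
                   ivd_instance_id(2L))
  # endplates straddling vertebra 4's superior junction derive from 3
  expect_identical(sort(unique(inst[sem == scheme_code("endplate")])),
                   endplate_instance_id(1:3))
})

test_that("a disc with no vertebra above falls back with a warning", {
  sem <- toy_volume(c(5, 20, 5))
  sem$data[2:4, 10:12, 2:4] <- scheme_code("corpus")
  sem$data[2:4, 3:4, 2:4] <- scheme_code("ivd")   # disc above everything
  inst <- toy_volume(c(5, 20, 5))
  inst$data[sem$data == scheme_code("corpus")] <- 1L
  expect_warning(out <- assign_disc_endplate_instances(sem, inst),
                 "no vertebra above")
  expect_true(all(out$data[sem$data == scheme_code("ivd")] ==
                    ivd_instance_id(1L)))
})

test_that("an error in one cutout stays local to its adjacent vertebrae", {
  ph <- small_phantom(10, seed = 21)
  cfg <- phantom_cutout_config(ph)
  oracle <- oracle_cutout_predictor(ph)
  corrupt_one <- function(k_bad) {
    function(cutout) {
      rel <- oracle(cutout)
      if (identical(cutout$rank, k_bad))
        rel <- corrupt_mask(rel, flip_rate = 0.1, boundary_jitter = 0.3,
                            seed = 99)
      rel
    }
  }
  base <- segment_instances(ph$semantic, oracle, cfg)$instances$data
  # a corrupted boundary cutout perturbs its vertebra (only two
  # appearances there, the corrupted center-role wins ties) ...
  pert1 <- suppressWarnings(
    segment_instances(ph$semantic, corrupt_one(1L), cfg))$instances$data
  changed <- which(vertebra_ids_only(base) != vertebra_ids_only(pert1))
  expect_gt(length(changed), 0)
  # ... but never beyond the adjacent vertebrae and their rim (0 = voxels
  # grown just outside the ground truth; post-processing removes those)
  expect_true(all(ph$instances$data[changed] %in% c(0L, 1L, 2L)))
  # an interior cutout is outvoted two-to-one by its intact neighbours
  pert5 <- suppressWarnings(
    segment_instances(ph$semantic, corrupt_one(5L), cfg))$instances$data
  changed5 <- which(vertebra_ids_only(base) != vertebra_ids_only(pert5))
  expect_true(all(ph$instances$data[changed5] %in% c(0L, 4:6)))
})
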