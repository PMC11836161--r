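make_pair <- function(ph) {
  res <- segment_instances(ph$semantic, oracle_cutout_predictor(ph),
                           phantom_cutout_config(ph))
  mask_pair(ph$semantic, res$instances)
}

test_that("unsupported instance voxels are cleared, semantic untouched", {
  ph <- small_phantom(3)
  pair <- make_pair(ph)
  # instance voxel over semantic background
  bg <- which(pair$semantic$data == 0L)[1]
  pair$instances$data[bg] <- 2L
  out <- remove_unsupported_instance_voxels(pair)
  expect_identical(out$instances$data[bg], 0L)
  expect_identical(out$semantic$data, ph$semantic$data)
  # already-consistent pair: identity
  clean <- make_pair(ph)
  expect_identical(remove_unsupported_instance_voxels(clean)$instances$data,
                   clean$instances$data)
  # fully disjoint masks leave an empty instance mask
  disj <- mask_pair(ph$semantic,
                    anat_volume(array(0L, vol_dim(ph$semantic)),
                                affine = ph$semantic$affine))
  disj$instances$data[ph$semantic$data == 0L][1:50] <- 1L
  expect_true(all(remove_unsupported_instance_voxels(disj)$instances$data
                  == 0L))
})

test_that("orphan semantic components are rescued by neighbour plurality", {
  sem <- toy_volume(c(6, 30, 6))
  inst <- toy_volume(c(6, 30, 6))
  sem$data[2:5, 2:10, 2:5] <- scheme_code("corpus")
  inst$data[2:5, 2:10, 2:5] <- 3L
  sem$data[2:5, 13:20, 2:5] <- scheme_code("corpus")
  inst$data[2:5, 13:20, 2:5] <- 4L
  # orphan spinous process touching instance 3 on a 4x4 face (16 voxels)
  # and instance 4 on a 2x2 face (4 voxels)
  sem$data[2:5, 11:12, 2:5] <- 0L
  sem$data[2:5, 11, 2:5] <- scheme_code("spinous_process")  # touches 3
  sem$data[2:3, 12, 2:3] <- scheme_code("spinous_process")  # touches 4
  out <- rescue_missing_components(mask_pair(sem, inst))
  expect_true(all(out$instances$data[sem$data ==
                                       scheme_code("spinous_process")] == 3L))
  # no orphans: identity
  pair <- make_pair(small_phantom(3))
  expect_identical(rescue_missing_components(pair)$instances$data,
                   pair$instances$data)
})

test_that("rescue ties go to the more superior instance id", {
  sem <- toy_volume(c(4, 20, 4))
  inst <- toy_volume(c(4, 20, 4))
  sem$data[2, 2:8, 2] <- scheme_code("corpus"); inst$data[2, 2:8, 2] <- 3L
  sem$data[2, 12:18, 2] <- scheme_code("corpus"); inst$data[2, 12:18, 2] <- 4L
  # orphan equidistant: touches 3 below and 4 above by one voxel each
  sem$data[2, 9:11, 2] <- scheme_code("arcus")
  out <- rescue_missing_components(mask_pair(sem, inst))
  expect_true(all(out$instances$data[2, 9:11, 2] == 3L))
})

test_that("isolated elements are removed, the largest always survives", {
  vol <- toy_volume(c(30, 30, 8))
  vol$data[5:20, 5:20, 3:6] <- 1L          # main component
  vol$data[29:30, 29:30, 7:8] <- 2L        # far blob, outside margin
  vol$data[22:23, 10:12, 4] <- 3L          # near blob, within 5-voxel margin
  out <- remove_isolated_elements(vol)
  expect_true(all(out$data[29:30, 29:30, 7:8] == 0L))
  expect_true(all(out$data[5:20, 5:20, 3:6] == 1L))
  expect_true(all(out$data[22:23, 10:12, 4] == 3L))
  # single component: identity
  single <- toy_volume(); single$data[2:4, 2:4, 2:4] <- 1L
  expect_identical(remove_isolated_elements(single)$data, single$data)
  empty <- toy_volume()
  expect_warning(out2 <- remove_isolated_elements(empty), "empty")
  expect_identical(out2$data, empty$data)
})

test_that("articular components are relabelled by majority, ties superior", {
  sem <- toy_volume(c(6, 20, 6))
  inst <- toy_volume(c(6, 20, 6))
  code <- scheme_code("articular_inferior_left")
  sem$data[2:5, 5:9, 2:6] <- code            # 4*5*5 = 100 voxels
  inst$data[2:5, 5:9, 2:6] <- 2L
  inst$data[2:5, 9, 2:4][1:5] <- 3L          # minority of 5 voxels
  out <- relabel_articular_processes(mask_pair(sem, inst))
  expect_true(all(out$instances$data[sem$data == code] == 2L))
  # homogeneous component: identity
  out2 <- relabel_articular_processes(out)
  expect_identical(out2$instances$data, out$instances$data)
  # exact 50/50 split: superior id wins
  sem2 <- toy_volume(c(4, 10, 4)); inst2 <- toy_volume(c(4, 10, 4))
  sem2$data[2, 2:5, 2] <- code
  inst2$data[2, 2:3, 2] <- 7L
  inst2$data[2, 4:5, 2] <- 6L
  out3 <- relabel_articular_processes(mask_pair(sem2, inst2))
  expect_true(all(out3$instances$data[2, 2:5, 2] == 6L))
})

test_that("every rule is idempotent on noisy pipeline output", {
  ph <- small_phantom(4, seed = 31)
  cfg <- phantom_cutout_config(ph)
  pr <- noisy_cutout_predictor(ph, flip_rate = 0.02, boundary_jitter = 0.1,
                               seed = 2)
  res <- suppressWarnings(segment_instances(ph$semantic, pr, cfg))
  pair <- mask_pair(ph$semantic, res$instances)
  for (rule in list(remove_unsupported_instance_voxels,
                    rescue_missing_components,
                    relabel_articular_processes)) {
    once <- suppressWarnings(rule(pair))
    twice <- suppressWarnings(rule(once))
    expect_identical(twice$instances$data, once$instances$data)
  }
  once <- remove_isolated_elements(res$instances)
  expect_identical(remove_isolated_elements(once)$data, once$data)
})

test_that("the full chain equalizes instance and semantic foregrounds", {
  ph <- small_phantom(5, seed = 17)
  pr <- noisy_cutout_predictor(ph, flip_rate = 0.02, boundary_jitter = 0.1,
                               seed = 8)
  res <- suppressWarnings(
    segment_instances(ph$semantic, pr, phantom_cutout_config(ph)))
  pair <- suppressWarnings(postprocess_pair(mask_pair(ph$semantic,
                                                      res$instances)))
  inst <- pair$instances$data
  sem <- pair$semantic$data
  expect_identical(which(sem %in% codes_in_group("vertebra")),
                   which(inst > 0L & inst < 100L))
  expect_identical(which(sem == scheme_code("ivd")),
                   which(inst >= 100L & inst < 200L))
  expect_identical(which(sem == scheme_code("endplate")),
                   which(inst >= 200L))
  expect_error(postprocess_pair(pair, skip = "nope"), "unknown rule")
})
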