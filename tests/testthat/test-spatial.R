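objects_from <- function(lab, vs = c(1, 1, 1)) spatial_objects_from_labels(lab, vs)

test_that("3D labelling is 26-connected and the size filter is strict", {
  d <- c(10, 20, 20)
  vol <- array(0, d)
  # one ~100-voxel sphere
  for (z in 3:7) for (y in 5:9) for (x in 5:9)
    if ((z - 5)^2 + (y - 7)^2 + (x - 7)^2 <= 6) vol[z, y, x] <- 100
  obj <- segment_objects_3d(vol, "manual", threshold = 50, min_size_vox = 10,
                            preprocess = FALSE)
  expect_length(obj, 1)
  # exactly 30 voxels is excluded under the strict > 30 rule
  vol30 <- array(0, d)
  vol30[2, 2:4, 2:11] <- 100          # 3 x 10 slab = 30 voxels
  expect_length(segment_objects_3d(vol30, "manual", threshold = 50,
                                   min_size_vox = 30, preprocess = FALSE), 0)
  vol31 <- vol30; vol31[2, 5, 2] <- 100
  expect_length(segment_objects_3d(vol31, "manual", threshold = 50,
                                   min_size_vox = 30, preprocess = FALSE), 1)
  # two spheres sharing a face merge under 26-connectivity
  two <- array(0, d)
  two[4:6, 4:6, 4:6] <- 100; two[4:6, 4:6, 7:9] <- 100
  expect_length(segment_objects_3d(two, "manual", threshold = 50,
                                   min_size_vox = 5, preprocess = FALSE), 1)
  expect_error(segment_objects_3d(array(1, d), "otsu", preprocess = FALSE),
               "constant")
})

test_that("boundary distance is symmetric, zero iff overlapping, and exact", {
  d <- c(12, 12, 12)
  lab <- array(0L, d)
  lab[6, 6, 2] <- 1L
  lab[6, 6, 12] <- 2L
  obj <- objects_from(lab)
  expect_equal(min_boundary_distance(obj[[1]], obj[[2]], units = "voxel"), 10)
  # physical scaling: xy pixel 0.065 um
  expect_equal(min_boundary_distance(obj[[1]], obj[[2]],
                                     voxel_size = c(0.3, 0.065, 0.065)),
               10 * 0.065, tolerance = 1e-12)
  # overlap -> 0
  lab2 <- array(0L, d); lab2[4:6, 4:6, 4:6] <- 1L
  a <- objects_from(lab2)[[1]]
  lab3 <- array(0L, d); lab3[5:8, 5:8, 5:8] <- 1L
  b <- objects_from(lab3)[[1]]
  expect_identical(min_boundary_distance(a, b), 0)
})

test_that("boundary distance equals the exhaustive all-pairs oracle", {
  set.seed(61)
  d <- c(14, 14, 14)
  for (i in 1:100) {
    va <- random_blob(d); vb <- random_blob(d)
    la <- array(0L, d); la[va] <- 1L
    lb <- array(0L, d); lb[vb] <- 1L
    a <- objects_from(la)[[1]]; b <- objects_from(lb)[[1]]
    expect_equal(min_boundary_distance(a, b, units = "voxel"),
                 bf_object_distance(va, vb, d), tolerance = 1e-12)
    expect_equal(min_boundary_distance(a, b, units = "voxel"),
                 min_boundary_distance(b, a, units = "voxel"))
  }
})

test_that("association fraction counts zero-distance ERES exactly", {
  d <- c(10, 16, 16)
  lds <- array(0L, d); lds[4:6, 4:6, 4:6] <- 1L
  eres <- array(0L, d)
  eres[5, 5, 5] <- 1L          # overlaps the LD
  eres[5, 13, 13] <- 2L        # distant
  out <- eres_ld_association(objects_from(eres), objects_from(lds),
                             units = "voxel")
  expect_equal(out$fraction, 0.5)
  expect_equal(out$distances$distance[out$distances$eres == 1], 0)
  # no LDs -> fraction 0, distances infinite
  out2 <- eres_ld_association(objects_from(eres), list(), units = "voxel")
  expect_equal(out2$fraction, 0)
  expect_true(all(is.infinite(out2$distances$distance)))
  # no ERES -> undefined, not 0
  expect_true(is.na(eres_ld_association(list(), objects_from(lds))$fraction))
})

test_that("simulated volumes reproduce requested boundary distances", {
  spec <- rbind(c(40, 0), c(40, 10), c(60, 4))
  sim <- simulate_volume(sim_config(poisson_scale = 0, read_noise_sd = 0,
                                    psf_sigma = 0),
                         spec, seed = 71, dim = c(20, 64, 64))
  expect_equal(sim$truth$eres_distance[1], 0)
  expect_lte(abs(sim$truth$eres_distance[2] - 10), 0.5)
  expect_lte(abs(sim$truth$eres_distance[3] - 4), 0.5)
  # certified ground truth agrees with the package's distance on truth labels
  er <- objects_from(sim$truth$eres)
  ld <- objects_from(sim$truth$lds)
  out <- eres_ld_association(er, ld, units = "voxel")
  expect_equal(sort(out$distances$distance), sort(sim$truth$eres_distance),
               tolerance = 1e-9)
  # empty spec -> no ERES objects
  sim0 <- simulate_volume(sim_config(), matrix(numeric(0), 0, 2), seed = 3,
                          dim = c(12, 32, 32))
  expect_equal(max(sim0$truth$eres), 0)
})

test_that("association is invariant to label permutation and rescaling", {
  spec <- rbind(c(40, 0), c(40, 0), c(40, 6), c(50, 3))
  sim <- simulate_volume(sim_config(poisson_scale = 0, read_noise_sd = 0,
                                    psf_sigma = 0),
                         spec, seed = 81, dim = c(20, 64, 64))
  er <- objects_from(sim$truth$eres); ld <- objects_from(sim$truth$lds)
  f1 <- eres_ld_association(er, ld, units = "voxel")$fraction
  expect_equal(f1, 0.5)
  f2 <- eres_ld_association(rev(er), rev(ld), units = "voxel")$fraction
  expect_equal(f2, f1)
  # intensity rescaling upstream does not change object-based association
  volx <- sim$volume$eres * 7.3
  obj <- segment_objects_3d(volx, "otsu", min_size_vox = 20, preprocess = FALSE)
  expect_length(obj, nrow(spec))
})

test_that("Pearson colocalization handles affine, anti-affine and noise", {
  set.seed(91)
  a <- matrix(runif(100 * 100), 100, 100)
  expect_equal(pearson_colocalization(a, 2 * a + 5), 1.0)
  expect_equal(pearson_colocalization(a, -a), -1.0)
  b <- matrix(runif(100 * 100), 100, 100)
  expect_lt(abs(pearson_colocalization(a, b)), 0.05)
  expect_error(pearson_colocalization(a, matrix(1, 100, 100)), "zero variance")
  roi <- matrix(FALSE, 100, 100); roi[1, 1] <- TRUE
  expect_error(pearson_colocalization(a, b, roi), ">= 2")
})
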