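test_that("confocal ratio recovers a constructed bimodal case", {
  # LD stain bimodal {0, 100}; protein 10 on the dilated LD region, 2 elsewhere
  n <- 24
  cell <- matrix(TRUE, n, n)
  ld_stain <- matrix(0, n, n); ld_stain[10:13, 10:13] <- 100
  dil <- matrix(FALSE, n, n); dil[9:14, 9:14] <- TRUE
  protein <- matrix(2, n, n); protein[dil] <- 10
  expect_equal(confocal_targeting_ratio(protein, cell, ld_stain), 5.0)
})

test_that("uniform protein gives ratio 1 regardless of threshold", {
  set.seed(3)
  n <- 20
  cell <- matrix(TRUE, n, n)
  ld_stain <- matrix(runif(n * n), n, n)
  expect_equal(confocal_targeting_ratio(matrix(7, n, n), cell, ld_stain), 1.0)
})

test_that("one-pixel dilation grows a square LD by exactly its boundary shell", {
  n <- 30
  cell <- matrix(TRUE, n, n)
  ld_stain <- matrix(0, n, n); ld_stain[11:16, 11:16] <- 100  # 6x6 square
  protein <- matrix(1, n, n)
  # measure mask2 area via pixel counting on both variants
  thr <- threshold_otsu(ld_stain[cell])
  base <- sum(ld_stain > thr)
  expect_equal(base, 36)
  dil <- ldscreen:::dilate1px(ld_stain > thr, "square")
  expect_equal(sum(dil), 8 * 8)  # (k+2)^2 for a square under a 3x3 element
  cross <- ldscreen:::dilate1px(ld_stain > thr, "cross")
  expect_equal(sum(cross), 36 + 4 * 6)  # cross adds one edge per side
})

test_that("nuclear exclusion removes nuclear pixels from mask 1", {
  n <- 20
  cell <- matrix(TRUE, n, n)
  nucl <- matrix(FALSE, n, n); nucl[1:10, ] <- TRUE
  ld_stain <- matrix(0, n, n); ld_stain[15:16, 15:16] <- 50
  protein <- matrix(1, n, n); protein[1:10, ] <- 100  # nucleoplasm-bright
  with_ex <- confocal_targeting_ratio(protein, cell, ld_stain,
                                      exclude_nuclear = nucl)
  without <- confocal_targeting_ratio(protein, cell, ld_stain)
  expect_equal(with_ex, 1.0)   # outside-LD mean no longer dominated by nucleus
  expect_lt(without, 1.0)
  expect_error(confocal_targeting_ratio(protein, nucl, ld_stain,
                                        exclude_nuclear = nucl),
               "empty after nuclear exclusion")
})

test_that("Otsu errors on constant input", {
  expect_error(threshold_otsu(rep(3, 10)), "constant")
  expect_error(confocal_targeting_ratio(matrix(1, 5, 5), matrix(TRUE, 5, 5),
                                        matrix(2, 5, 5)), "constant")
})

test_that("Huang threshold separates a clear bimodal mixture", {
  set.seed(8)
  v <- c(rnorm(600, 10, 1), rnorm(300, 60, 3))
  thr <- threshold_huang(v)
  # separates the modes: nearly all low-mode mass below, high mode above
  expect_gt(thr, 10); expect_lt(thr, 50)
  expect_gt(mean(v[v > thr]) , 50)
  # crisp bimodal case lands between the two values
  thr2 <- threshold_huang(c(rep(0, 50), rep(100, 50)))
  expect_gt(thr2, 0); expect_lt(thr2, 100)
  expect_error(threshold_huang(rep(1, 5)), "constant")
})

test_that("marker area near LDs matches constructed fractions", {
  n <- 40
  roi <- matrix(TRUE, n, n)
  ld <- matrix(0, n, n); ld[10:19, 10:19] <- 100
  # marker entirely within the dilated LD region
  m1 <- matrix(0, n, n); m1[12:15, 12:15] <- 50
  expect_equal(area_near_ld_fraction(m1, ld, roi), 1.0)
  # marker far away (> 1 px from LDs)
  m2 <- matrix(0, n, n); m2[30:35, 30:35] <- 50
  expect_equal(area_near_ld_fraction(m2, ld, roi), 0.0)
  # constructed half-overlap: 4x8 marker, half inside dilated LD box (9:20)
  m3 <- matrix(0, n, n); m3[13:16, 17:24] <- 50
  expect_equal(area_near_ld_fraction(m3, ld, roi), 0.5)
})
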