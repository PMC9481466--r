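null_screen <- function(n_genes = 300, seed = 1, n_replicates = 2) {
  lay <- generate_screen_layout(1, 384, n_replicates, make_gene_table(n_genes),
                                seed = seed)
  simulate_screen_wells(lay, seed = seed + 1)
}

test_that("hit calls respect strict cutoffs and retain Z-scores", {
  wells <- null_screen(seed = 3)
  res <- score_screen(wells)
  # force known Z values through packaged constants on synthetic rows
  res$z[1] <- -5.5; res$z[2] <- -2.5; res$z[3] <- 2.5001; res$z[4] <- -3.0
  res$z_cell_count[4] <- -3.0
  called <- call_hits(res)
  expect_equal(called$hit[1], "decrease")
  expect_equal(called$hit[2], "none")      # -2.5 exactly: strict inequality
  expect_equal(called$hit[3], "increase")
  expect_equal(called$hit[4], "none")      # demoted by cell-death flag
  expect_true(called$flag_cell_death[4])
  expect_equal(called$z[4], -3.0)          # Z retained after demotion
})

test_that("excluded gene categories are demoted", {
  wells <- null_screen(seed = 9)
  res <- score_screen(wells)
  res$z[5] <- 6
  called <- call_hits(res, excluded_genes = res$gene[5])
  expect_true(called$flag_excluded_category[5])
  expect_equal(called$hit[5], "none")
})

test_that("scoring is affine-invariant when constants are recomputed", {
  wells <- null_screen(seed = 11)
  res1 <- score_screen(wells)
  shifted <- wells
  shifted$ratio_median <- shifted$ratio_median + 3
  res2 <- score_screen(shifted)
  expect_equal(res2$z, res1$z, tolerance = 1e-10)
})

test_that("degenerate screens error out", {
  wells <- null_screen(seed = 2)
  wells$ratio_median <- 2.0
  expect_error(score_screen(wells), "degenerate")
  wells2 <- null_screen(seed = 2)
  wells2$ratio_median <- NA_real_
  expect_error(score_screen(wells2), "undefined")
})

test_that("replicate correlation matches trivial and analytic cases", {
  wells <- null_screen(seed = 21)
  # replicate 2 identical to replicate 1 -> r = 1
  w1 <- wells[wells$replicate == 1, ]
  w2 <- w1; w2$replicate <- 2
  expect_equal(replicate_correlation(rbind(w1, w2)), 1.0)
  # centred anti-correlated replicate -> r = -1
  w3 <- w1
  w3$replicate <- 2
  w3$ratio_median <- 2 * mean(w1$ratio_median, na.rm = TRUE) - w1$ratio_median
  expect_equal(replicate_correlation(rbind(w1, w3)), -1.0)
  # too few pairs
  expect_error(replicate_correlation(rbind(w1[1:2, ], w2[1:2, ])), ">= 3")
})

test_that("replicate correlation matches the variance-ratio expectation", {
  # X_ir = r (1 + b_i + e_ir): expected Pearson r = sb^2 / (sb^2 + sw^2)
  lay <- generate_screen_layout(2, 384, 2, make_gene_table(700), seed = 31)
  wells <- simulate_screen_wells(lay, seed = 32)
  expected <- screen_noise_config()$shared_var_frac
  expect_lt(abs(replicate_correlation(wells) - expected), 0.05)
})

test_that("planted decrease hits are recalled and cell-death wells demoted", {
  lay <- generate_screen_layout(1, 384, 2, make_gene_table(372), seed = 41)
  ds <- make_gene_table(372)$dsrna_id
  dec <- ds[1:19]                          # ~5% planted decreases
  death <- ds[20:29]                       # decreased ratio + cell death
  effects <- data.frame(
    dsrna_id = c(dec, death),
    true_ratio = 2.147287 * 0.5,
    cell_count_multiplier = c(rep(1, length(dec)), rep(0.25, length(death))))
  wells <- simulate_screen_wells(lay, effects, seed = 42)
  res <- call_hits(score_screen(wells))
  recall <- mean(res$hit[match(dec, res$dsrna_id)] == "decrease")
  expect_gte(recall, 0.9)
  died <- res[match(death, res$dsrna_id), ]
  expect_true(all(died$flag_cell_death))
  expect_true(all(died$hit == "none"))
})

test_that("gene-level call picks the dsRNA with the largest |Z|", {
  lay <- generate_screen_layout(1, 384, 2, make_gene_table(100, 2), seed = 51)
  wells <- simulate_screen_wells(lay, seed = 52)
  res <- call_hits(score_screen(wells))
  g <- gene_calls(res)
  expect_equal(nrow(g), 100)
  one <- res[res$gene == g$gene[1], ]
  expect_equal(g$z[1], one$z[which.max(abs(one$z))])
})
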