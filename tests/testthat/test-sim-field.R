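test_that("noise-free simulation reproduces the true ratio exactly on truth masks", {
  cfg <- clean_cfg()
  for (r in c(1, 2.5, 5, 10)) {
    fs <- simulate_field(ground_truth_effect(true_ratio = r), cfg, seed = 7)
    for (i in seq_len(max(fs$truth$cells))) {
      got <- cell_targeting_ratio(fs$image$protein, fs$truth$cells == i,
                                  fs$truth$lds > 0)
      if (is.finite(got)) expect_equal(got, r, tolerance = 1e-6)
    }
  }
})

test_that("true ratio is recovered on truth masks within 10% at default noise", {
  cfg <- test_cfg(cell_ratio_cv = 0)
  cm <- af_control_mean(cfg)
  ratios <- unlist(lapply(1:20, function(s) {
    fs <- simulate_field(ground_truth_effect(true_ratio = 5), cfg, seed = s)
    p <- autofluorescence_correct(fs$image$protein, cm)
    vapply(seq_len(max(fs$truth$cells)), function(i)
      cell_targeting_ratio(p, fs$truth$cells == i, fs$truth$lds > 0), 1)
  }))
  expect_lt(abs(mean(ratios, na.rm = TRUE) / 5 - 1), 0.10)
})

test_that("simulation is bit-identical for the same seed and differs across seeds", {
  cfg <- test_cfg()
  a <- simulate_field(ground_truth_effect(true_ratio = 3), cfg, seed = 5)
  b <- simulate_field(ground_truth_effect(true_ratio = 3), cfg, seed = 5)
  expect_identical(a, b)
  c <- simulate_field(ground_truth_effect(true_ratio = 3), cfg, seed = 6)
  expect_false(identical(a$image$protein, c$image$protein))
})

test_that("ground-truth masks are mutually consistent", {
  cfg <- test_cfg()
  for (s in 1:5) {
    fs <- simulate_field(ground_truth_effect(true_ratio = 2), cfg, seed = s)
    tr <- fs$truth
    # nuclei sit inside their own cell
    expect_true(all(tr$cells[tr$nuclei > 0] == tr$nuclei[tr$nuclei > 0]))
    # each LD lies inside exactly one cell, the recorded owner
    for (l in seq_len(max(tr$lds))) {
      owners <- unique(tr$cells[tr$lds == l])
      expect_length(owners, 1)
      expect_equal(owners, unname(tr$ld_cell[as.character(l)]))
    }
  }
})

test_that("zero cells yields empty masks and a pure background field", {
  cfg <- clean_cfg(cells_per_field = 0)
  fs <- simulate_field(ground_truth_effect(true_ratio = 5), cfg, seed = 1)
  expect_equal(max(fs$truth$cells), 0)
  expect_equal(max(fs$truth$lds), 0)
  expect_true(all(fs$image$protein == 0))
})

test_that("autofluorescence-control wells carry no protein signal", {
  cfg <- clean_cfg(autofluorescence_level = 50, background_level = 10)
  fs <- simulate_field(ground_truth_effect(true_ratio = 5), cfg, seed = 2,
                       role = "autofluorescence_control")
  expect_true(all(fs$image$protein == 60))
  expect_gt(max(fs$truth$cells), 0)  # cells are present, just unexpressed
})

test_that("nonpositive true ratio is rejected", {
  expect_error(ground_truth_effect(true_ratio = 0), "> 0")
  expect_error(ground_truth_effect(true_ratio = -2), "> 0")
  expect_error(ground_truth_effect(cell_count_multiplier = 0), "> 0")
})

test_that("wells derive distinct deterministic per-field seeds", {
  cfg <- test_cfg(image_size = 96L, cells_per_field = 3L,
                  cell_radius_range = c(10, 13))
  eff <- ground_truth_effect(true_ratio = 2)
  w <- simulate_well("A01", eff, cfg, n_fields = 3, seed = 9, plate = 1)
  expect_length(w, 3)
  expect_false(identical(w[[1]]$image$protein, w[[2]]$image$protein))
  # n_fields = 1 equals simulate_field at the derived sub-seed
  w1 <- simulate_well("A01", eff, cfg, n_fields = 1, seed = 9, plate = 1)
  f1 <- simulate_field(eff, cfg, seed = derive_seed(9, 1, "A01", 1))
  expect_identical(w1[[1]], f1)
  # same seed, different wells -> different images
  v <- simulate_well("B02", eff, cfg, n_fields = 1, seed = 9, plate = 1)
  expect_false(identical(w1[[1]]$image$protein, v[[1]]$image$protein))
})
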