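# Shared fixtures, built in code at test time.

# Desk-scale field configuration used throughout the suite.
test_cfg <- function(...) {
  args <- utils::modifyList(
    list(image_size = 160L, cells_per_field = 5L,
         cell_radius_range = c(14, 19), lds_per_cell = 6),
    list(...))
  do.call(sim_config, args)
}

# Same geometry with optics/noise/offsets off: ratios on ground-truth masks
# are exact by construction.
clean_cfg <- function(...) {
  args <- utils::modifyList(
    list(background_level = 0, autofluorescence_level = 0, psf_sigma = 0,
         poisson_scale = 0, read_noise_sd = 0, cell_ratio_cv = 0),
    list(...))
  do.call(test_cfg, args)
}

# Classifiers are expensive to train; train once per test run and reuse.
.fixture_env <- new.env(parent = emptyenv())
test_classifiers <- function() {
  if (is.null(.fixture_env$cls))
    .fixture_env$cls <- train_screen_classifiers(test_cfg(), n_annotated = 7L,
                                                 seed = 11L)
  .fixture_env$cls
}

af_control_mean <- function(cfg) cfg$background_level + cfg$autofluorescence_level

# Independent sorted-list oracles for the robust statistics.
bf_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}
bf_mad <- function(x) bf_median(abs(x - bf_median(x)))
bf_robust_z <- function(xi, x) (xi - bf_median(x)) / (1.4826 * bf_mad(x))

# Exhaustive all-voxel-pairs distance oracle (independent of the package's
# boundary-based implementation).
bf_object_distance <- function(voxA, voxB, d, scale = c(1, 1, 1)) {
  if (length(intersect(voxA, voxB)) > 0L) return(0)
  pa <- arrayInd(voxA, d); pb <- arrayInd(voxB, d)
  min(sqrt(outer(pa[, 1] * scale[1], pb[, 1] * scale[1], "-")^2 +
           outer(pa[, 2] * scale[2], pb[, 2] * scale[2], "-")^2 +
           outer(pa[, 3] * scale[3], pb[, 3] * scale[3], "-")^2))
}

# Random compact 3D blob for distance tests.
random_blob <- function(d, n_seed_vox = 8L) {
  ctr <- c(sample(3:(d[1] - 2), 1), sample(3:(d[2] - 2), 1),
           sample(3:(d[3] - 2), 1))
  vox <- unique(c(
    (ctr[3] - 1L) * d[1] * d[2] + (ctr[2] - 1L) * d[1] + ctr[1],
    replicate(n_seed_vox, {
      p <- pmin(pmax(ctr + sample(-1:1, 3, replace = TRUE), 1), d)
      (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
    })))
  vox
}
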