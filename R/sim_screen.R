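## Well-level screen generative model ---------------------------------------

#' Noise model for well-level screen simulation
#'
#' Dispersion of the per-well median targeting ratio \eqn{X_i} around its
#' true value, split into a component shared between replicate screens
#' (plate/position and reagent-efficacy effects) and an independent
#' within-replicate component. Defaults reproduce the dispersion of the
#' original genome-scale screen: total relative sd
#' \eqn{1.4826 \times 0.113917 / 2.147287 \approx 7.9\%}, of which a
#' fraction 0.7645 of the variance is replicate-shared — so the expected
#' Pearson correlation between replicates equals that fraction by the
#' standard variance-ratio identity \eqn{r = \sigma_b^2/(\sigma_b^2+\sigma_w^2)}.
#'
#' @param total_rel_sd total relative sd of \eqn{X_i} around the true ratio.
#' @param shared_var_frac fraction of that variance shared between replicates.
#' @param baseline_cells expected cells per well (all fields pooled).
#' @param baseline_ld_area_rel expected per-cell LD area fraction.
#' @param ld_area_rel_sd relative sd of the well LD-area readout.
#' @return list of class \code{screen_noise}.
#' @export
screen_noise_config <- function(total_rel_sd = 1.4826 * 0.113917 / 2.147287,
                                shared_var_frac = 0.7645,
                                baseline_cells = 160,
                                baseline_ld_area_rel = 0.05,
                                ld_area_rel_sd = 0.10) {
  stopifnot(total_rel_sd >= 0, shared_var_frac >= 0, shared_var_frac <= 1)
  structure(list(total_rel_sd = total_rel_sd,
                 shared_var_frac = shared_var_frac,
                 baseline_cells = baseline_cells,
                 baseline_ld_area_rel = baseline_ld_area_rel,
                 ld_area_rel_sd = ld_area_rel_sd),
            class = "screen_noise")
}

#' Simulate per-well screen readouts without rendering images
#'
#' Generates \code{well_records} (the same table the image pipeline produces
#' via segmentation and [aggregate_well()]) directly from ground-truth
#' effects, for testing the hit-calling statistics at full screen scale.
#' Positive controls get ratio multipliers 0.5 (decrease) and 1.6
#' (increase); autofluorescence wells carry no ratio readout.
#'
#' @param layout a \code{plate_layout} (see [generate_screen_layout()]).
#' @param effects data.frame with \code{dsrna_id} and any of
#'   \code{true_ratio}, \code{cell_count_multiplier},
#'   \code{ld_area_multiplier}; unlisted reagents are null.
#' @param noise a [screen_noise_config()].
#' @param baseline_ratio true ratio of null wells.
#' @param seed integer seed.
#' @return data.frame of class \code{well_records}: \code{plate},
#'   \code{replicate}, \code{well}, \code{gene}, \code{dsrna_id},
#'   \code{role}, \code{ratio_median}, \code{cell_count},
#'   \code{ld_area_rel}, \code{n_cells_with_ratio}.
#' @export
simulate_screen_wells <- function(layout, effects = NULL,
                                  noise = screen_noise_config(),
                                  baseline_ratio = 2.147287, seed = 1L) {
  stopifnot(inherits(layout, "data.frame"))
  df <- as.data.frame(layout)
  with_seed(seed, {
    n <- nrow(df)
    true_ratio <- rep(baseline_ratio, n)
    cmult <- rep(1, n); amult <- rep(1, n)
    if (!is.null(effects)) {
      m <- match(df$dsrna_id, effects$dsrna_id)
      hit <- !is.na(m)
      if (!is.null(effects$true_ratio))
        true_ratio[hit] <- effects$true_ratio[m[hit]]
      if (!is.null(effects$cell_count_multiplier))
        cmult[hit] <- effects$cell_count_multiplier[m[hit]]
      if (!is.null(effects$ld_area_multiplier))
        amult[hit] <- effects$ld_area_multiplier[m[hit]]
    }
    true_ratio[df$role == "control_pos_decrease"] <-
      baseline_ratio * 0.5
    true_ratio[df$role == "control_pos_increase"] <-
      baseline_ratio * 1.6

    ## replicate-shared well effect keyed by (plate, well): same physical
    ## reagent position in both replicate screens
    key <- paste(df$plate, df$well)
    uk <- unique(key)
    sd_b <- noise$total_rel_sd * sqrt(noise$shared_var_frac)
    sd_w <- noise$total_rel_sd * sqrt(1 - noise$shared_var_frac)
    b <- stats::setNames(rnorm(length(uk), 0, sd_b), uk)
    x <- true_ratio * (1 + b[key] + rnorm(n, 0, sd_w))
    x <- pmax(x, 1e-6)
    x[df$role == "autofluorescence_control"] <- NA_real_

    cells <- rpois(n, noise$baseline_cells * cmult * pmax(1 + b[key], 0.05))
    ld_area <- noise$baseline_ld_area_rel * amult *
      exp(rnorm(n, 0, noise$ld_area_rel_sd))
    nwr <- rbinom(n, cells, 0.9)

    out <- data.frame(plate = df$plate, replicate = df$replicate,
                      well = df$well, gene = df$gene, dsrna_id = df$dsrna_id,
                      role = df$role, ratio_median = x, cell_count = cells,
                      ld_area_rel = ld_area, n_cells_with_ratio = nwr,
                      stringsAsFactors = FALSE)
    class(out) <- c("well_records", "data.frame")
    out
  })
}
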