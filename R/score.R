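## Robust-Z scoring and hit calling -----------------------------------------

#' Score a screen's well records with robust Z-scores
#'
#' Combines replicate well readouts per dsRNA (mean of the replicate
#' medians), then standardizes the targeting ratio, cell count and relative
#' LD area each with their own median/MAD over library wells. When
#' \code{constants} is omitted the targeting constants are estimated from
#' this run's library wells (controls excluded, replicates pooled by
#' default); pass [screen_constants()] to normalize against the published
#' genome-screen distribution instead.
#'
#' @param wells a \code{well_records} data.frame (see [aggregate_well()],
#'   [simulate_screen_wells()]).
#' @param constants optional [screen_constants()] for the targeting ratio.
#' @param pool_replicates estimate constants from all replicates pooled
#'   (default) rather than replicate 1 only.
#' @return data.frame of class \code{screen_result}, one row per dsRNA:
#'   gene, per-replicate and combined readouts, \code{z} (targeting),
#'   \code{z_cell_count}, \code{z_ld_area}. Attributes carry the constants
#'   used.
#' @export
score_screen <- function(wells, constants = NULL, pool_replicates = TRUE) {
  stopifnot(inherits(wells, "data.frame"), nrow(wells) > 0)
  lib <- wells[wells$role == "library" & !is.na(wells$dsrna_id), , drop = FALSE]
  if (nrow(lib) == 0L) stopf("no library wells with reagents to score")
  if (all(!is.finite(lib$ratio_median)))
    stopf("all library well readouts are undefined")

  est <- if (pool_replicates) lib else lib[lib$replicate == min(lib$replicate), ]
  xs <- est$ratio_median[is.finite(est$ratio_median)]
  if (is.null(constants)) {
    ctr <- stats::median(xs); spr <- mad_raw(xs)
    if (spr == 0) stopf("degenerate screen: MAD of library readouts is 0")
    constants <- screen_constants(ctr, spr)
  }

  ## combine replicates per dsRNA
  reps <- sort(unique(lib$replicate))
  sp <- split(lib, lib$dsrna_id)
  rows <- lapply(sp, function(d) {
    xr <- vapply(reps, function(r) {
      v <- d$ratio_median[d$replicate == r]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, 1)
    cc <- mean(d$cell_count, na.rm = TRUE)
    la <- mean(d$ld_area_rel, na.rm = TRUE)
    out <- data.frame(dsrna_id = d$dsrna_id[1], gene = d$gene[1],
                      x = mean(xr[is.finite(xr)]),
                      cell_count = cc, ld_area_rel = la,
                      stringsAsFactors = FALSE)
    for (i in seq_along(reps)) out[[sprintf("x_rep%d", reps[i])]] <- xr[i]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  res$z <- robust_z(res$x, constants)
  zc <- function(v) {
    v_ok <- v[is.finite(v)]
    spr <- mad_raw(v_ok)
    if (spr == 0) return(rep(NA_real_, length(v)))
    robust_z(v, screen_constants(stats::median(v_ok), spr))
  }
  res$z_cell_count <- zc(res$cell_count)
  res$z_ld_area <- zc(res$ld_area_rel)

  attr(res, "constants") <- constants
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Call screen hits with the cut-off and exclusion filters
#'
#' A dsRNA is a \code{decrease} candidate when its targeting-ratio robust Z
#' is below \code{-z_cutoff} and an \code{increase} candidate above
#' \code{+z_cutoff} (strict inequalities). Candidates are then demoted to
#' \code{none} -- but keep their Z -- when knockdown caused significant cell
#' death (cell-count Z below \code{cell_death_cutoff}), extremely small LDs
#' (LD-area Z below \code{small_ld_cutoff}, which makes the ratio
#' unreliable), or the gene belongs to an excluded category (e.g. ribosomal
#' / proteasomal / spliceosomal).
#'
#' @param results a [score_screen()] result.
#' @param z_cutoff targeting-ratio cutoff (default 2.5).
#' @param cell_death_cutoff cell-count Z threshold (default -2.5).
#' @param small_ld_cutoff LD-area Z threshold (default -2.5).
#' @param excluded_genes character vector of genes to exclude.
#' @return the input with logical columns \code{flag_cell_death},
#'   \code{flag_small_ld}, \code{flag_excluded_category} and factor-like
#'   \code{hit} in \{decrease, increase, none\}.
#' @export
call_hits <- function(results, z_cutoff = 2.5, cell_death_cutoff = -2.5,
                      small_ld_cutoff = -2.5, excluded_genes = character()) {
  stopifnot(inherits(results, "screen_result"))
  hit <- rep("none", nrow(results))
  hit[results$z < -z_cutoff] <- "decrease"
  hit[results$z > z_cutoff] <- "increase"
  results$flag_cell_death <- is.finite(results$z_cell_count) &
    results$z_cell_count < cell_death_cutoff
  results$flag_small_ld <- is.finite(results$z_ld_area) &
    results$z_ld_area < small_ld_cutoff
  results$flag_excluded_category <- results$gene %in% excluded_genes
  flagged <- results$flag_cell_death | results$flag_small_ld |
    results$flag_excluded_category
  hit[flagged] <- "none"
  results$hit <- hit
  attr(results, "cutoffs") <- list(z = z_cutoff, cell_death = cell_death_cutoff,
                                   small_ld = small_ld_cutoff)
  results
}

#' Gene-level calls from dsRNA-level results
#'
#' Libraries target genes one to two times; the gene-level call is the
#' dsRNA with the largest absolute targeting Z.
#'
#' @param results a [call_hits()] result.
#' @return data.frame with one row per gene.
#' @export
gene_calls <- function(results) {
  stopifnot(inherits(results, "screen_result"))
  sp <- split(as.data.frame(results), results$gene)
  out <- do.call(rbind, lapply(sp, function(d) d[which.max(abs(d$z)), ]))
  rownames(out) <- NULL
  out
}

#' Pearson correlation of replicate well readouts
#'
#' Pairs replicate screens by (plate, well) over library wells with a
#' defined readout in both replicates and returns the standard Pearson
#' correlation coefficient (the screen's replicate-concordance statistic).
#'
#' @param wells a \code{well_records} data.frame with >= 2 replicates.
#' @param replicates which two replicates to pair (default first two).
#' @return Pearson r.
#' @export
replicate_correlation <- function(wells, replicates = NULL) {
  stopifnot(inherits(wells, "data.frame"))
  lib <- wells[wells$role == "library" & !is.na(wells$dsrna_id), ]
  reps <- sort(unique(lib$replicate))
  if (is.null(replicates)) replicates <- reps[1:2]
  if (length(reps) < 2L) stopf("need >= 2 replicates")
  a <- lib[lib$replicate == replicates[1], ]
  b <- lib[lib$replicate == replicates[2], ]
  m <- merge(a[, c("plate", "well", "ratio_median")],
             b[, c("plate", "well", "ratio_median")], by = c("plate", "well"))
  ok <- is.finite(m$ratio_median.x) & is.finite(m$ratio_median.y)
  if (sum(ok) < 3L) stopf("need >= 3 wells with both replicates defined")
  stats::cor(m$ratio_median.x[ok], m$ratio_median.y[ok])
}

#' @export
print.screen_result <- function(x, ...) {
  cons <- attr(x, "constants")
  cat(sprintf("Screen result: %d dsRNAs, %d genes\n",
              nrow(x), length(unique(x$gene))))
  cat(sprintf("  targeting constants: median %.6g, MAD %.6g\n",
              cons$median, cons$mad))
  if (!is.null(x$hit)) {
    tab <- table(factor(x$hit, c("decrease", "increase", "none")))
    cat(sprintf("  hits: %d decrease, %d increase (%d flagged/none)\n",
                tab[["decrease"]], tab[["increase"]], tab[["none"]]))
  }
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  cat(sprintf("dsRNAs scored: %d\n", nrow(object)))
  cat(sprintf("targeting Z range: [%.2f, %.2f]\n",
              min(object$z, na.rm = TRUE), max(object$z, na.rm = TRUE)))
  if (!is.null(object$hit)) {
    cat("calls:\n"); print(table(object$hit))
    cat(sprintf("flags: cell_death %d, small_ld %d, excluded_category %d\n",
                sum(object$flag_cell_death), sum(object$flag_small_ld),
                sum(object$flag_excluded_category)))
  }
  invisible(object)
}
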