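#' Screen normalization constants
#'
#' Container for the centre and spread used to convert per-well median
#' targeting ratios into robust Z-scores. The defaults are the constants of
#' the original genome-scale GPAT4 targeting screen (median 2.147287, median
#' absolute deviation 0.113917); pass \code{median}/\code{mad} computed from
#' your own run to normalize against it instead.
#'
#' @param median screen median of the per-well readouts \eqn{X_i}.
#' @param mad unscaled median absolute deviation,
#'   \eqn{\mathrm{median}(|X_i - \mathrm{median}(X)|)}.
#' @param scale consistency constant relating MAD to the standard deviation
#'   under normality; 1.4826 by convention.
#' @return an object of class \code{screen_constants}.
#' @seealso [robust_z()], [score_screen()]
#' @export
screen_constants <- function(median = 2.147287, mad = 0.113917, scale = 1.4826) {
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median))
    stopf("'median' must be a single finite number")
  if (!is.numeric(mad) || length(mad) != 1L || !is.finite(mad) || mad < 0)
    stopf("'mad' must be a single finite number >= 0")
  structure(list(median = median, mad = mad, scale = scale),
            class = "screen_constants")
}

#' @export
print.screen_constants <- function(x, ...) {
  cat(sprintf("Screen constants: median = %g, MAD = %g (scale %g)\n",
              x$median, x$mad, x$scale))
  invisible(x)
}

#' Median absolute deviation (unscaled)
#'
#' \eqn{\mathrm{MAD}(X) = \mathrm{median}(|X_i - \mathrm{median}(X)|)}, with
#' no consistency scaling (contrast \code{stats::mad}, whose default constant
#' is 1.4826). This is the spread estimate entering the robust Z-score.
#'
#' @param x numeric vector with at least one finite value; \code{NA}s dropped.
#' @return non-negative scalar.
#' @export
mad_raw <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stopf("mad_raw: no finite values")
  stats::mad(x, constant = 1)
}

#' Robust Z-score of a well readout
#'
#' \deqn{Z = (X_i - \mathrm{median}(X)) / (1.4826 \times \mathrm{MAD}(X))}
#'
#' Median/MAD standardization resistant to the outliers that genuine screen
#' hits produce; under normality Z is asymptotically standard normal.
#'
#' @param x readout value(s) \eqn{X_i} (vectorized).
#' @param constants a [screen_constants()] object giving median and MAD;
#'   defaults to the packaged genome-screen constants.
#' @return numeric vector of Z-scores.
#' @examples
#' robust_z(2.147287)                      # screen centre -> 0
#' robust_z(c(1, 5), screen_constants(3, 1))
#' @export
robust_z <- function(x, constants = screen_constants()) {
  if (!inherits(constants, "screen_constants"))
    stopf("'constants' must be a screen_constants object")
  if (constants$mad <= 0)
    stopf("degenerate spread: screen MAD is %g (must be > 0)", constants$mad)
  (x - constants$median) / (constants$scale * constants$mad)
}
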