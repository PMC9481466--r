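## Confocal-image targeting metrics -----------------------------------------

#' Automatic thresholds on in-ROI intensities
#'
#' Both thresholds are computed on a 256-bin histogram of the values inside
#' the region of interest, with bin edges from the in-ROI minimum/maximum.
#' \code{threshold_otsu} maximizes between-class variance (via
#' \code{EBImage::otsu}); \code{threshold_huang} minimizes Huang's fuzzy
#' entropy with membership based on the distance to the class means (the
#' ImageJ "Huang" method, implemented here).
#'
#' @param values numeric vector of in-ROI intensities.
#' @param levels number of histogram bins.
#' @return threshold value; foreground is \code{value > threshold}.
#' @export
threshold_otsu <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stopf("no values to threshold")
  rg <- range(values)
  if (diff(rg) == 0) stopf("Otsu threshold undefined on constant values")
  EBImage::otsu(matrix(values, 1L), range = rg, levels = levels)
}

#' @rdname threshold_otsu
#' @export
threshold_huang <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stopf("no values to threshold")
  rg <- range(values)
  if (diff(rg) == 0) stopf("Huang threshold undefined on constant values")
  bin <- pmin(floor((values - rg[1]) / diff(rg) * levels), levels - 1L)
  h <- tabulate(bin + 1L, nbins = levels)
  k <- seq_len(levels) - 1L
  wcum <- cumsum(h); scum <- cumsum(h * k)
  wtot <- wcum[levels]; stot <- scum[levels]
  C <- levels - 1L
  hf <- function(u) { # fuzzy entropy, 0 at u in {0,1}
    v <- numeric(length(u))
    ok <- u > 0 & u < 1
    v[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    v
  }
  best_t <- 0L; best_s <- Inf
  for (t in 0:(levels - 2L)) {
    w0 <- wcum[t + 1L]; w1 <- wtot - w0
    if (w0 == 0L || w1 == 0L) next
    mu0 <- scum[t + 1L] / w0
    mu1 <- (stot - scum[t + 1L]) / w1
    mu <- ifelse(k <= t, mu0, mu1)
    u <- 1 / (1 + abs(k - mu) / C)
    s <- sum(h * hf(u))
    if (s < best_s) { best_s <- s; best_t <- t }
  }
  rg[1] + (best_t + 0.5) / levels * diff(rg)
}

dilate1px <- function(mask, shape = c("square", "cross")) {
  shape <- match.arg(shape)
  brush <- if (shape == "square") EBImage::makeBrush(3L, "box") else
    EBImage::makeBrush(3L, "diamond")
  as.matrix(EBImage::dilate(EBImage::Image(as_mask(mask) * 1), brush)) > 0
}

#' Confocal LD targeting ratio with Otsu segmentation and 1-pixel dilation
#'
#' The manual-outline variant of the targeting ratio: within the drawn cell
#' outline (mask 1) the LD-stain channel is Otsu-thresholded, the LD mask is
#' dilated by one pixel to include LD surfaces (mask 2, intersected with
#' mask 1), and the ratio is the mean protein intensity in mask 2 over the
#' mean in mask 1 minus mask 2. A nuclear mask may be excluded from mask 1
#' first (used for nucleoplasm-rich markers such as CCT1).
#'
#' @param protein protein-channel matrix.
#' @param cell_mask binary manual cell outline (mask 1), nonempty.
#' @param ld_stain LD-stain channel matrix.
#' @param exclude_nuclear optional binary nuclear mask removed from mask 1.
#' @param dilate_ld dilate the LD mask by one pixel (the confocal protocol);
#'   \code{FALSE} gives the screen-style undilated variant.
#' @param dilate_shape 1-pixel dilation element: 3x3 \code{"square"}
#'   (8-connected, default) or \code{"cross"}.
#' @return positive scalar, or \code{NA_real_} when mask 2 is empty.
#' @export
confocal_targeting_ratio <- function(protein, cell_mask, ld_stain,
                                     exclude_nuclear = NULL,
                                     dilate_ld = TRUE,
                                     dilate_shape = "square") {
  cell_mask <- as_mask(cell_mask)
  if (!any(cell_mask)) stopf("empty cell mask")
  if (!is.null(exclude_nuclear)) cell_mask <- cell_mask & !as_mask(exclude_nuclear)
  if (!any(cell_mask)) stopf("cell mask empty after nuclear exclusion")
  thr <- threshold_otsu(ld_stain[cell_mask])
  ld_mask <- ld_stain > thr & cell_mask
  if (dilate_ld) ld_mask <- dilate1px(ld_mask, dilate_shape)
  mask2 <- ld_mask & cell_mask
  rest <- cell_mask & !mask2
  if (!any(mask2) || !any(rest)) return(NA_real_)
  mean(protein[mask2]) / mean(protein[rest])
}

#' Fraction of a marker's area lying within one pixel of LDs
#'
#' The marker channel is Otsu-thresholded and the LD channel
#' Huang-thresholded inside the ROI; the LD mask is dilated by one pixel and
#' the returned value is the fraction of marker-mask pixels falling inside
#' the dilated LD mask (used for ERES markers such as Tango1/Sec23).
#'
#' @param marker marker-channel matrix.
#' @param ld LD-channel matrix.
#' @param roi binary region of interest, nonempty.
#' @param dilate_shape see [confocal_targeting_ratio()].
#' @return fraction in \code{[0, 1]}, or \code{NA_real_} if the marker mask
#'   is empty.
#' @export
area_near_ld_fraction <- function(marker, ld, roi, dilate_shape = "square") {
  roi <- as_mask(roi)
  if (!any(roi)) stopf("empty roi")
  if (!identical(dim(marker), dim(ld)) || !identical(dim(ld), dim(roi)))
    stopf("marker/ld/roi shapes differ")
  marker_mask <- marker > threshold_otsu(marker[roi]) & roi
  if (!any(marker_mask)) return(NA_real_)
  ld_mask <- ld > threshold_huang(ld[roi]) & roi
  ld_dil <- dilate1px(ld_mask, dilate_shape)
  sum(marker_mask & ld_dil) / sum(marker_mask)
}
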