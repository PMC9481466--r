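## Object segmentation -------------------------------------------------------

#' Label nuclei from a binary foreground mask
#'
#' 8-connected components, components smaller than \code{min_area_px}
#' removed, remaining objects labelled 1..K.
#'
#' @param foreground binary (logical or 0/1) matrix.
#' @param min_area_px minimum object area in pixels (default 50 at
#'   0.065 um/px).
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(foreground, min_area_px = 50L) {
  if (!is_binary_mask(foreground)) stopf("foreground must be a binary mask")
  lab <- label_components_2d(foreground)
  if (max(lab) > 0L && min_area_px > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(lab)
}

#' Label lipid droplets from a binary foreground mask
#'
#' Same component rule as [segment_nuclei()] with an LD-scale default
#' minimum area.
#'
#' @inheritParams segment_nuclei
#' @export
segment_lds <- function(foreground, min_area_px = 4L) {
  segment_nuclei(foreground, min_area_px)
}

#' Partition cell foreground into cells by nucleus-seeded watershed
#'
#' Seeded watershed on an elevation surface, restricted to the cell
#' foreground: flooding starts from the nucleus labels and each foreground
#' pixel joins the seed it is reached from first, so there is exactly one
#' cell region per nucleus and cell labels equal their seed nucleus labels.
#' Foreground pixels unreachable from any seed stay background. The
#' elevation is the inverted, smoothed cell-probability map when one is
#' supplied, else the inverted distance transform of the foreground.
#'
#' @param foreground binary cell-foreground mask.
#' @param nuclei nucleus label matrix (the seeds).
#' @param probability optional cell foreground-probability map of the same
#'   shape (see [pixel_probability()]).
#' @param smooth_sigma Gaussian smoothing of the elevation surface, px.
#' @return integer label matrix; attribute \code{border_labels} lists cells
#'   touching the image border.
#' @export
segment_cells <- function(foreground, nuclei, probability = NULL,
                          smooth_sigma = 2) {
  if (!is_binary_mask(foreground)) stopf("foreground must be a binary mask")
  if (!identical(dim(foreground), dim(nuclei)))
    stopf("foreground and nuclei shapes differ")
  fg <- as_mask(foreground)
  if (max(nuclei) == 0L) {
    warning("no nuclei seeds; returning empty cell mask")
    out <- matrix(0L, nrow(fg), ncol(fg))
    attr(out, "border_labels") <- integer(0)
    return(out)
  }
  elev <- if (!is.null(probability)) {
    if (!identical(dim(probability), dim(fg)))
      stopf("probability map shape differs from foreground")
    max(probability) - gauss_filter(probability, smooth_sigma)
  } else {
    dm <- as.matrix(EBImage::distmap(EBImage::Image(fg * 1)))
    max(dm) - dm
  }
  seeds <- EBImage::Image(nuclei)
  lab <- EBImage::propagate(EBImage::Image(elev), seeds, mask = fg)
  out <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  ## seeds can slightly overhang the foreground; keep them in their cells
  out[nuclei > 0L] <- nuclei[nuclei > 0L]
  border <- unique(c(out[1, ], out[nrow(out), ], out[, 1], out[, ncol(out)]))
  attr(out, "border_labels") <- sort(border[border > 0L])
  out
}

#' Assign lipid droplets to cells by maximal intersection area
#'
#' Each LD goes to the cell whose region it overlaps most; ties break to the
#' smaller cell label. LDs that intersect no cell are unassigned (\code{NA})
#' and excluded from downstream per-cell measurements.
#'
#' @param lds LD label matrix.
#' @param cells cell label matrix of the same shape.
#' @return named integer vector: names are LD labels, values the assigned
#'   cell label or \code{NA}.
#' @export
assign_lds_to_cells <- function(lds, cells) {
  if (!identical(dim(lds), dim(cells))) stopf("label mask shapes differ")
  n_ld <- max(lds)
  if (n_ld == 0L)
    return(stats::setNames(integer(0), character(0)))
  sel <- lds > 0L & cells > 0L
  out <- rep(NA_integer_, n_ld)
  if (any(sel)) {
    tab <- table(ld = lds[sel], cell = cells[sel])
    cell_ids <- as.integer(colnames(tab))
    for (r in seq_len(nrow(tab))) {
      counts <- tab[r, ]
      best <- cell_ids[which(counts == max(counts))]
      out[as.integer(rownames(tab)[r])] <- min(best)  # tie -> smaller label
    }
  }
  stats::setNames(out, as.character(seq_len(n_ld)))
}
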