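## Targeting-ratio quantification -------------------------------------------

#' Subtract plate autofluorescence from the protein channel
#'
#' Pixelwise subtraction of the mean intensity of the plate's
#' autofluorescence-control images, clipped at zero. The targeting ratio is
#' scale-invariant but not offset-invariant, so this correction is what
#' makes ratios comparable across plates.
#'
#' @param protein_channel 2D matrix (protein/FITC channel).
#' @param control_mean mean control-image intensity (>= 0).
#' @return corrected matrix.
#' @export
autofluorescence_correct <- function(protein_channel, control_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L ||
      !is.finite(control_mean) || control_mean < 0)
    stopf("control_mean must be a single finite number >= 0")
  pmax(protein_channel - control_mean, 0)
}

#' Per-cell LD targeting ratio
#'
#' Mean protein intensity inside the cell's LD mask divided by the mean
#' outside the LD mask but within the cell mask. Undefined (\code{NA}) when
#' the cell has no LD pixels or the outside mean is not positive; such cells
#' are excluded from the well median but still counted as cells.
#'
#' @param protein corrected protein channel matrix.
#' @param cell_mask binary mask of one cell (nonempty).
#' @param ld_mask binary mask of LD pixels (intersected with the cell).
#' @return positive scalar, or \code{NA_real_} when undefined.
#' @export
cell_targeting_ratio <- function(protein, cell_mask, ld_mask) {
  cell_mask <- as_mask(cell_mask); ld_mask <- as_mask(ld_mask)
  if (!any(cell_mask)) stopf("empty cell mask")
  inside <- cell_mask & ld_mask
  outside <- cell_mask & !ld_mask
  if (!any(inside) || !any(outside)) return(NA_real_)
  denom <- mean(protein[outside])
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  mean(protein[inside]) / denom
}

#' Measure every cell of one segmented field
#'
#' Applies [cell_targeting_ratio()] per cell using the LDs assigned to it by
#' [assign_lds_to_cells()], producing the per-cell record table of the
#' screen pipeline.
#'
#' @param protein corrected protein channel.
#' @param cells cell label matrix.
#' @param lds LD label matrix.
#' @param assignment LD-to-cell assignment (default computed here).
#' @param plate,well,field identifiers carried into the records.
#' @return data.frame with one row per segmented cell: \code{plate},
#'   \code{well}, \code{field}, \code{cell}, \code{targeting_ratio},
#'   \code{cell_area_px}, \code{ld_area_px}, \code{ld_count}.
#' @export
quantify_field <- function(protein, cells, lds,
                           assignment = assign_lds_to_cells(lds, cells),
                           plate = 1L, well = NA_character_, field = 1L) {
  if (!identical(dim(protein), dim(cells)) || !identical(dim(cells), dim(lds)))
    stopf("protein/cells/lds shapes differ")
  labs <- sort(unique(cells[cells > 0L]))
  recs <- lapply(labs, function(cl) {
    cell_mask <- cells == cl
    my_lds <- as.integer(names(assignment))[!is.na(assignment) & assignment == cl]
    ld_mask <- if (length(my_lds)) matrix(lds %in% my_lds, nrow(lds)) else
      matrix(FALSE, nrow(lds), ncol(lds))
    data.frame(plate = plate, well = well, field = field, cell = cl,
               targeting_ratio = cell_targeting_ratio(protein, cell_mask, ld_mask),
               cell_area_px = sum(cell_mask),
               ld_area_px = sum(cell_mask & ld_mask),
               ld_count = length(my_lds))
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(plate = integer(0), well = character(0), field = integer(0),
               cell = integer(0), targeting_ratio = numeric(0),
               cell_area_px = integer(0), ld_area_px = integer(0),
               ld_count = integer(0))
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Aggregate one well's cell records into the well readout
#'
#' The final per-dsRNA readout \eqn{X_i} is the median targeting ratio over
#' all cells with a defined ratio, pooled across the well's fields (standard
#' median: mean of the two central values for even counts). The cell count
#' includes ratio-undefined cells, since the cell-death filter uses total
#' cells.
#'
#' @param cell_records data.frame from [quantify_field()] (rows of one well).
#' @param gene,dsrna_id,role,replicate metadata carried into the record.
#' @return one-row data.frame: \code{plate}, \code{replicate}, \code{well},
#'   \code{gene}, \code{dsrna_id}, \code{role}, \code{ratio_median},
#'   \code{cell_count}, \code{ld_area_rel}, \code{n_cells_with_ratio}.
#' @export
aggregate_well <- function(cell_records, gene = NA_character_,
                           dsrna_id = NA_character_, role = "library",
                           replicate = 1L) {
  if (nrow(cell_records) > 0L) {
    if (length(unique(paste(cell_records$plate, cell_records$well))) != 1L)
      stopf("cell records span more than one (plate, well)")
  }
  ratios <- cell_records$targeting_ratio
  defined <- is.finite(ratios)
  x <- if (any(defined)) stats::median(ratios[defined]) else NA_real_
  rel_area <- if (nrow(cell_records))
    stats::median(cell_records$ld_area_px / cell_records$cell_area_px) else NA_real_
  out <- data.frame(
    plate = if (nrow(cell_records)) cell_records$plate[1] else NA_integer_,
    replicate = replicate,
    well = if (nrow(cell_records)) cell_records$well[1] else NA_character_,
    gene = gene, dsrna_id = dsrna_id, role = role,
    ratio_median = x,
    cell_count = nrow(cell_records),
    ld_area_rel = rel_area,
    n_cells_with_ratio = sum(defined),
    stringsAsFactors = FALSE)
  class(out) <- c("well_records", "data.frame")
  out
}
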