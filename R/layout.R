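## Plate layouts -------------------------------------------------------------

WELL_ROLES <- c("library", "control_lacz", "control_pos_decrease",
                "control_pos_increase", "autofluorescence_control")

#' Normalize and validate well coordinates
#'
#' Accepts forms like \code{"A1"}, \code{"a01"} and returns letter + two-digit
#' form (\code{"A01"}). For a 384-well plate rows span A-P and columns 1-24.
#'
#' @param well character vector of well coordinates.
#' @param n_wells plate format (default 384; 96 also understood).
#' @return normalized character vector.
#' @export
normalize_well <- function(well, n_wells = 384L) {
  m <- regmatches(well, regexec("^([A-Za-z])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("malformed well coordinate(s): %s",
                      paste(well[bad], collapse = ", "))
  row <- toupper(vapply(m, `[`, "", 2L))
  col <- as.integer(vapply(m, `[`, "", 3L))
  nrow <- if (n_wells == 96L) 8L else 16L
  ncol <- if (n_wells == 96L) 12L else 24L
  ok <- match(row, LETTERS) <= nrow & col >= 1L & col <= ncol
  if (any(!ok)) stopf("well coordinate(s) outside the %d-well grid: %s",
                      n_wells, paste(well[!ok], collapse = ", "))
  sprintf("%s%02d", row, col)
}

well_grid <- function(n_wells = 384L) {
  nrow <- if (n_wells == 96L) 8L else 16L
  ncol <- if (n_wells == 96L) 12L else 24L
  as.vector(t(outer(LETTERS[seq_len(nrow)], seq_len(ncol),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' Generate a gene table for a synthetic dsRNA library
#'
#' Names follow the arrayed-library convention of one to two independent
#' dsRNA reagents per gene.
#'
#' @param n_genes number of genes.
#' @param dsrnas_per_gene reagents per gene (1 or 2; recycled).
#' @return data.frame with columns \code{gene}, \code{dsrna_id}.
#' @export
make_gene_table <- function(n_genes, dsrnas_per_gene = 1L) {
  genes <- sprintf("gene%05d", seq_len(n_genes))
  reps <- rep_len(dsrnas_per_gene, n_genes)
  data.frame(
    gene = rep(genes, reps),
    dsrna_id = unlist(lapply(seq_len(n_genes), function(i)
      sprintf("ds%05d_%d", i, seq_len(reps[i])))),
    stringsAsFactors = FALSE)
}

#' Generate a replicated multi-plate screen layout
#'
#' Lays out an arrayed dsRNA library over \code{n_plates} 384-well plates,
#' replicated \code{n_replicates} times with identical gene placement per
#' replicate. Each plate carries control wells: LacZ negative controls,
#' positive controls expected to decrease / increase the targeting readout,
#' and wells reserved for measuring plate autofluorescence. Library reagents
#' are placed at randomized positions (the screening-centre convention);
#' library wells beyond the reagent count stay empty.
#'
#' @param n_plates plates per replicate.
#' @param wells_per_plate plate format (default 384).
#' @param n_replicates replicate screens (default 2).
#' @param gene_table data.frame with \code{gene} and \code{dsrna_id}
#'   (see [make_gene_table()]); \code{NULL} fills every library well.
#' @param seed integer seed controlling the randomized placement.
#' @param controls_per_plate named integer vector with elements
#'   \code{control_lacz}, \code{control_pos_decrease},
#'   \code{control_pos_increase}, \code{autofluorescence_control}.
#' @return data.frame (class \code{plate_layout}) with columns
#'   \code{plate}, \code{replicate}, \code{well}, \code{gene},
#'   \code{dsrna_id}, \code{role}; one row per well record.
#' @examples
#' lay <- generate_screen_layout(1, 384, 1, make_gene_table(10), seed = 1)
#' table(lay$role)
#' @export
generate_screen_layout <- function(n_plates, wells_per_plate = 384L,
                                   n_replicates = 2L, gene_table = NULL,
                                   seed = 1L,
                                   controls_per_plate = c(
                                     control_lacz = 8L,
                                     control_pos_decrease = 1L,
                                     control_pos_increase = 1L,
                                     autofluorescence_control = 2L)) {
  stopifnot(n_plates >= 1L, wells_per_plate >= 1L, n_replicates >= 1L)
  nctrl <- sum(controls_per_plate)
  if (nctrl >= wells_per_plate)
    stopf("more control wells per plate (%d) than wells (%d)", nctrl, wells_per_plate)
  lib_per_plate <- wells_per_plate - nctrl
  n_lib_wells <- n_plates * lib_per_plate
  if (is.null(gene_table)) gene_table <- make_gene_table(n_lib_wells)
  if (nrow(gene_table) == 0L) stopf("gene_table is empty")
  overflow <- nrow(gene_table) - n_lib_wells
  if (overflow > 0L)
    stopf("library has %d more reagents than available library wells (%d > %d)",
          overflow, nrow(gene_table), n_lib_wells)

  with_seed(seed, {
    wells <- well_grid(wells_per_plate)[seq_len(wells_per_plate)]
    ## control wells drawn at random positions per plate, identical across
    ## replicates (plates are replicated as-is)
    plates <- lapply(seq_len(n_plates), function(p) {
      pos <- sample(wells)
      role <- rep("library", wells_per_plate)
      k <- 0L
      for (r in names(controls_per_plate)) {
        nr <- controls_per_plate[[r]]
        if (nr > 0L) { role[(k + 1L):(k + nr)] <- r; k <- k + nr }
      }
      data.frame(plate = p, well = pos, role = role, stringsAsFactors = FALSE)
    })
    lay <- do.call(rbind, plates)
    lay$gene <- NA_character_
    lay$dsrna_id <- NA_character_
    lib_idx <- which(lay$role == "library")
    take <- sample(lib_idx, nrow(gene_table))
    lay$gene[take] <- gene_table$gene
    lay$dsrna_id[take] <- gene_table$dsrna_id
    lay$gene[lay$role == "control_lacz"] <- "LacZ"
    lay$gene[lay$role == "control_pos_decrease"] <- "betaCOP"
    lay$gene[lay$role == "control_pos_increase"] <- "seipin"
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      x <- lay; x$replicate <- r; x
    }))
    out <- out[, c("plate", "replicate", "well", "gene", "dsrna_id", "role")]
    out <- out[order(out$replicate, out$plate, out$well), ]
    rownames(out) <- NULL
    class(out) <- c("plate_layout", "data.frame")
    out
  })
}

#' Read / write plate layouts as CSV
#'
#' The CSV has columns \code{plate}, \code{replicate} (optional, default 1),
#' \code{well}, \code{gene}, \code{dsrna_id}, \code{role}. Well coordinates
#' are normalized; duplicate wells within a (plate, replicate) and unknown
#' role strings are rejected with row numbers.
#'
#' @param path file path.
#' @return \code{read_plate_layout}: a \code{plate_layout} data.frame.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("layout file is empty: %s", path)
  need <- c("plate", "well", "gene", "dsrna_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("layout missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(df$replicate)) df$replicate <- 1L
  bad_role <- which(!df$role %in% WELL_ROLES)
  if (length(bad_role))
    stopf("unknown role '%s' at row %d", df$role[bad_role[1]], bad_role[1])
  df$well <- normalize_well(df$well)
  key <- paste(df$plate, df$replicate, df$well)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicate well %s in plate %s (row %d)",
          df$well[dup[1]], df$plate[dup[1]], dup[1])
  df <- df[, c("plate", "replicate", "well", "gene", "dsrna_id", "role")]
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' @rdname read_plate_layout
#' @param layout a \code{plate_layout} data.frame.
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
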