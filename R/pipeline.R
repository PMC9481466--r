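## Pipeline orchestration ----------------------------------------------------

#' Configuration of a full pipeline run
#'
#' A run is fully determined by its configuration and seed. Two simulate
#' modes exist: \code{"wells"} draws per-well readouts from the well-level
#' generative model (screen-scale statistics without rendering images);
#' \code{"images"} renders, segments and quantifies field images for every
#' well of the layout and is meant for small layouts.
#'
#' @param out_dir output directory (created if needed).
#' @param mode simulate mode, \code{"wells"} or \code{"images"}.
#' @param n_plates,wells_per_plate,n_replicates layout dimensions.
#' @param gene_table optional library table (see [make_gene_table()]).
#' @param effects optional ground-truth effects data.frame
#'   (\code{dsrna_id}, \code{true_ratio}, ...).
#' @param sim a [sim_config()] (images mode).
#' @param noise a [screen_noise_config()] (wells mode).
#' @param constants \code{NULL} to estimate screen constants from the run,
#'   or a [screen_constants()] (e.g. the packaged genome-screen constants).
#' @param z_cutoff,cell_death_cutoff,small_ld_cutoff,excluded_genes hit
#'   calling parameters, see [call_hits()].
#' @param n_fields fields per well in images mode.
#' @param n_annotated annotated training fields per classifier.
#' @param seed master seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir, mode = c("wells", "images"), n_plates = 1L,
                       wells_per_plate = 384L, n_replicates = 2L,
                       gene_table = NULL, effects = NULL,
                       sim = sim_config(), noise = screen_noise_config(),
                       constants = NULL, z_cutoff = 2.5,
                       cell_death_cutoff = -2.5, small_ld_cutoff = -2.5,
                       excluded_genes = character(), n_fields = 2L,
                       n_annotated = 7L, seed = 1L) {
  structure(list(out_dir = out_dir, mode = match.arg(mode),
                 n_plates = n_plates, wells_per_plate = wells_per_plate,
                 n_replicates = n_replicates, gene_table = gene_table,
                 effects = effects, sim = sim, noise = noise,
                 constants = constants, z_cutoff = z_cutoff,
                 cell_death_cutoff = cell_death_cutoff,
                 small_ld_cutoff = small_ld_cutoff,
                 excluded_genes = excluded_genes, n_fields = n_fields,
                 n_annotated = n_annotated, seed = seed),
            class = "run_config")
}

#' Train the three compartment classifiers on simulated annotated fields
#'
#' Emulates the screen's training protocol: a handful of annotated images
#' per model (default 7), nuclei and cells learned from the nuclei channel,
#' LDs from the LD-stain channel, labels taken from the simulator's
#' ground-truth masks.
#'
#' @param cfg a [sim_config()].
#' @param n_annotated annotated fields per model.
#' @param seed RNG seed.
#' @return named list of [train_pixel_classifier()] models
#'   (\code{nucleus}, \code{cell}, \code{ld}).
#' @export
train_screen_classifiers <- function(cfg = sim_config(), n_annotated = 7L,
                                     seed = 1L) {
  fields <- lapply(seq_len(n_annotated), function(i)
    simulate_field(ground_truth_effect(true_ratio = cfg$baseline_ratio), cfg,
                   seed = derive_seed(seed, "train", i)))
  ann <- function(channel, truth_mask) {
    lapply(fields, function(f)
      list(image = f$image[[channel]],
           labels = matrix(1L + (f$truth[[truth_mask]] > 0L),
                           nrow(f$truth[[truth_mask]]))))
  }
  list(nucleus = train_pixel_classifier(ann("nuclei", "nuclei"), "nucleus",
                                        seed = derive_seed(seed, "rf", "nucleus")),
       cell = train_pixel_classifier(ann("nuclei", "cells"), "cell",
                                     seed = derive_seed(seed, "rf", "cell")),
       ld = train_pixel_classifier(ann("ld", "lds"), "ld",
                                   seed = derive_seed(seed, "rf", "ld")))
}

#' Segment and quantify one field image
#'
#' The per-field analysis of the screen: classify pixels of the three
#' compartments, label nuclei, partition cells by nucleus-seeded watershed
#' on the cell-probability relief, label LDs, assign LDs to cells, correct
#' the protein channel for plate autofluorescence and measure every cell.
#'
#' @param image a \code{field_image}.
#' @param classifiers list from [train_screen_classifiers()].
#' @param control_mean plate autofluorescence control mean for the protein
#'   channel.
#' @param min_nucleus_area,min_ld_area component size filters, px.
#' @param plate,well,field identifiers for the records.
#' @return list with \code{records} (data.frame from [quantify_field()]) and
#'   the label masks \code{nuclei}, \code{cells}, \code{lds}.
#' @export
analyze_field <- function(image, classifiers, control_mean = 0,
                          min_nucleus_area = 50L, min_ld_area = 4L,
                          plate = 1L, well = NA_character_, field = 1L) {
  nuc_fg <- classify_pixels(classifiers$nucleus, image$nuclei)
  cell_prob <- pixel_probability(classifiers$cell, image$nuclei)
  ld_fg <- classify_pixels(classifiers$ld, image$ld)
  nuclei <- segment_nuclei(nuc_fg, min_nucleus_area)
  cells <- segment_cells(cell_prob >= 0.5, nuclei, probability = cell_prob)
  lds <- segment_lds(ld_fg, min_ld_area)
  protein <- autofluorescence_correct(image$protein, control_mean)
  recs <- quantify_field(protein, cells, lds, plate = plate, well = well,
                         field = field)
  list(records = recs, nuclei = nuclei, cells = cells, lds = lds)
}

#' Run the screen pipeline
#'
#' Executes the requested stages in order, writing per-stage CSV outputs and
#' a JSON run report to \code{config$out_dir}. Reruns with the same
#' configuration are deterministic.
#'
#' @param config a [run_config()].
#' @param stages subset of \code{c("simulate", "train", "segment",
#'   "quantify", "score")} (\code{train}/\code{segment}/\code{quantify}
#'   apply to images mode; in wells mode the simulate stage yields well
#'   records directly).
#' @return invisible list: the run report (also written as
#'   \code{run_report.json}).
#' @export
run_pipeline <- function(config, stages = c("simulate", "score")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("ldscreen")),
                 seed = config$seed, mode = config$mode, stages = stages)
  layout <- NULL; wells <- NULL; fields <- NULL; classifiers <- NULL

  if ("simulate" %in% stages) {
    layout <- generate_screen_layout(config$n_plates, config$wells_per_plate,
                                     config$n_replicates, config$gene_table,
                                     seed = config$seed)
    write_plate_layout(layout, file.path(config$out_dir, "layout.csv"))
    report$n_well_records <- nrow(layout)
    if (config$mode == "wells") {
      wells <- simulate_screen_wells(layout, config$effects, config$noise,
                                     baseline_ratio = config$sim$baseline_ratio,
                                     seed = config$seed)
      write_well_records(wells, file.path(config$out_dir, "well_records.csv"))
    } else {
      eff_tab <- config$effects
      fields <- lapply(seq_len(nrow(layout)), function(i) {
        row <- layout[i, ]
        eff <- ground_truth_effect(row$dsrna_id)
        if (!is.null(eff_tab) && !is.na(row$dsrna_id)) {
          m <- match(row$dsrna_id, eff_tab$dsrna_id)
          if (!is.na(m)) eff <- ground_truth_effect(
            row$dsrna_id,
            true_ratio = if (!is.null(eff_tab$true_ratio)) eff_tab$true_ratio[m] else config$sim$baseline_ratio,
            cell_count_multiplier = if (!is.null(eff_tab$cell_count_multiplier)) eff_tab$cell_count_multiplier[m] else 1,
            ld_area_multiplier = if (!is.null(eff_tab$ld_area_multiplier)) eff_tab$ld_area_multiplier[m] else 1)
        }
        simulate_well(row$well, eff, config$sim, n_fields = config$n_fields,
                      seed = derive_seed(config$seed, "rep", row$replicate),
                      plate = row$plate, role = row$role)
      })
      names(fields) <- paste(layout$plate, layout$replicate, layout$well)
    }
  } else {
    lp <- file.path(config$out_dir, "layout.csv")
    if (!file.exists(lp)) stopf("missing input for stage: %s", lp)
    layout <- read_plate_layout(lp)
  }

  if ("train" %in% stages && config$mode == "images") {
    classifiers <- train_screen_classifiers(config$sim, config$n_annotated,
                                            seed = config$seed)
    report$classifier_oob_accuracy <-
      vapply(classifiers, function(m) m$meta$oob_accuracy, 1)
  }

  if (any(c("segment", "quantify") %in% stages) && config$mode == "images") {
    if (is.null(fields)) stopf("missing input for stage: simulated fields")
    if (is.null(classifiers))
      classifiers <- train_screen_classifiers(config$sim, config$n_annotated,
                                              seed = config$seed)
    ## plate autofluorescence control mean per (plate, replicate)
    af_key <- paste(layout$plate, layout$replicate)
    control_mean <- vapply(unique(af_key), function(k) {
      sel <- which(af_key == k & layout$role == "autofluorescence_control")
      if (length(sel) == 0L)
        return(config$sim$background_level + config$sim$autofluorescence_level)
      mean(vapply(sel, function(i)
        mean(vapply(fields[[i]], function(f) mean(f$image$protein), 1)), 1))
    }, 1)
    all_wells <- lapply(seq_len(nrow(layout)), function(i) {
      row <- layout[i, ]
      cm <- control_mean[[paste(row$plate, row$replicate)]]
      recs <- do.call(rbind, lapply(seq_along(fields[[i]]), function(f)
        analyze_field(fields[[i]][[f]]$image, classifiers, cm,
                      plate = row$plate, well = row$well, field = f)$records))
      aggregate_well(recs, gene = row$gene, dsrna_id = row$dsrna_id,
                     role = row$role, replicate = row$replicate)
    })
    wells <- do.call(rbind, all_wells)
    class(wells) <- c("well_records", "data.frame")
    write_well_records(wells, file.path(config$out_dir, "well_records.csv"))
  }

  if ("score" %in% stages) {
    if (is.null(wells)) {
      wp <- file.path(config$out_dir, "well_records.csv")
      if (!file.exists(wp)) stopf("missing input for stage: %s", wp)
      wells <- read_well_records(wp)
    }
    res <- score_screen(wells, constants = config$constants)
    res <- call_hits(res, config$z_cutoff, config$cell_death_cutoff,
                     config$small_ld_cutoff, config$excluded_genes)
    write_screen_result(res, file.path(config$out_dir, "screen_result.csv"))
    cons <- attr(res, "constants")
    report$constants <- list(median = cons$median, mad = cons$mad,
                             scale = cons$scale)
    report$cutoffs <- attr(res, "cutoffs")
    report$n_dsrna <- nrow(res)
    report$hits <- as.list(table(res$hit))
    report$flags <- list(cell_death = sum(res$flag_cell_death),
                         small_ld = sum(res$flag_small_ld),
                         excluded_category = sum(res$flag_excluded_category))
    if (length(unique(wells$replicate)) >= 2L)
      report$replicate_correlation <- replicate_correlation(wells)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
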