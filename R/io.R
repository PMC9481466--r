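## File formats --------------------------------------------------------------

## Images and label masks travel as 16-bit TIFF; intensities are camera
## units in [0, 65535], stored by tiff as [0, 1].
TIFF_MAX <- 65535

#' Write / read a multi-channel field image as 16-bit TIFF
#'
#' Channel order: protein, nuclei, LD stain. Intensities are clipped to the
#' 16-bit camera range; pixel size travels in the JSON sidecar written next
#' to the image (\code{<path>.json}).
#'
#' @param image a \code{field_image} (see [simulate_field()]).
#' @param path output path (`.tif`).
#' @return \code{read_field_tiff}: a \code{field_image}.
#' @export
write_field_tiff <- function(image, path) {
  chans <- lapply(image[c("protein", "nuclei", "ld")],
                  function(x) pmin(pmax(round(x), 0), TIFF_MAX) / TIFF_MAX)
  tiff::writeTIFF(chans, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            channels = c("protein", "nuclei", "ld")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  chans <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list(pixel_size_um = NA_real_)
  structure(list(protein = chans[[1]] * TIFF_MAX,
                 nuclei = chans[[2]] * TIFF_MAX,
                 ld = chans[[3]] * TIFF_MAX,
                 pixel_size_um = as.numeric(meta$pixel_size_um)),
            class = "field_image")
}

#' Write / read an integer label mask as 16-bit TIFF
#' @param mask integer label matrix.
#' @param path file path.
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > TIFF_MAX) stopf("more than %d labels", TIFF_MAX)
  tiff::writeTIFF(mask / TIFF_MAX, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stopf("mask not found: %s", path)
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * TIFF_MAX)), nrow(m), ncol(m))
}

#' Write / read well-record and screen-result tables as CSV
#' @param x the table.
#' @param path file path.
#' @export
write_well_records <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_records
#' @export
read_well_records <- function(path) {
  if (!file.exists(path)) stopf("well records not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("well_records", "data.frame")
  df
}

#' @rdname write_well_records
#' @export
write_screen_result <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_records
#' @export
read_screen_result <- function(path) {
  if (!file.exists(path)) stopf("screen result not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("screen_result", "data.frame")
  df
}

#' Serialize / load a simulation configuration as YAML
#' @param cfg a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  do.call(sim_config, yaml::read_yaml(path))
}
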