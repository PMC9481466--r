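## Object-based 3D colocalization -------------------------------------------

#' Build spatial objects from a 3D label array
#'
#' A spatial object carries its voxel set, boundary voxel set (voxels with
#' at least one background 26-neighbour or touching the volume edge) and
#' size.
#'
#' @param labels 3D integer label array (0 = background).
#' @param voxel_size physical voxel dimensions \code{c(z, y, x)} in um.
#' @return list of objects of class \code{spatial_object}.
#' @export
spatial_objects_from_labels <- function(labels, voxel_size = c(0.3, 0.065, 0.065)) {
  d <- dim(labels)
  stopifnot(length(d) == 3L)
  labs <- sort(unique(labels[labels > 0L]))
  lapply(labs, function(l) {
    vox <- which(labels == l)
    structure(list(label = l, voxels = vox,
                   boundary = boundary_of(vox, d),
                   size = length(vox), dim = d, voxel_size = voxel_size),
              class = "spatial_object")
  })
}

#' Segment 3D objects from a volume channel
#'
#' Pre-processes the channel (large-scale background subtraction and a
#' median filter, both per z-slice), binarizes it by automatic or manual
#' intensity thresholding, labels 26-connected components, and keeps only
#' objects strictly larger than \code{min_size_vox} voxels (the size filter
#' excluding debris and non-specific labelling).
#'
#' @param volume 3D numeric array (z, y, x).
#' @param threshold_method \code{"otsu"}, \code{"huang"} or \code{"manual"}.
#' @param threshold manual threshold value (required for
#'   \code{threshold_method = "manual"}).
#' @param min_size_vox strict lower size bound in voxels (default 30).
#' @param preprocess apply background subtraction + median filter.
#' @param background_sigma Gaussian scale of the subtracted background, px.
#' @param median_radius median filter radius, px (0 = off).
#' @param voxel_size physical voxel dimensions \code{c(z, y, x)}, um.
#' @return list of \code{spatial_object}s.
#' @export
segment_objects_3d <- function(volume,
                               threshold_method = c("otsu", "huang", "manual"),
                               threshold = NULL, min_size_vox = 30L,
                               preprocess = TRUE, background_sigma = 16,
                               median_radius = 1L,
                               voxel_size = c(0.3, 0.065, 0.065)) {
  threshold_method <- match.arg(threshold_method)
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  x <- volume
  if (preprocess) {
    mx <- max(x)
    if (mx > 0) for (z in seq_len(d[1])) {
      sl <- x[z, , ]
      sl <- pmax(sl - gauss_filter(sl, background_sigma), 0)
      if (median_radius > 0L && max(sl) > 0) {
        sl <- as.matrix(EBImage::medianFilter(sl / max(sl), median_radius)) * max(sl)
      }
      x[z, , ] <- sl
    }
  }
  thr <- switch(threshold_method,
                otsu = threshold_otsu(as.numeric(x)),
                huang = threshold_huang(as.numeric(x)),
                manual = {
                  if (is.null(threshold)) stopf("manual threshold requires 'threshold'")
                  threshold
                })
  lab <- label_components_3d(x > thr)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes <= min_size_vox)  # strict: keep only size > min
    if (length(drop)) lab[array(lab %in% drop, d)] <- 0L
    lab <- relabel_consecutive(lab)
  }
  spatial_objects_from_labels(lab, voxel_size)
}

#' Minimum boundary-to-boundary distance between two 3D objects
#'
#' Zero when the voxel sets overlap; otherwise the minimum anisotropy-scaled
#' Euclidean distance between boundary voxel centres. \code{units = "voxel"}
#' ignores the physical voxel dimensions (parity with voxel-space tools).
#'
#' @param a,b \code{spatial_object}s from the same volume.
#' @param voxel_size physical voxel dimensions \code{c(z, y, x)} in um
#'   (defaults to those stored in \code{a}).
#' @param units \code{"um"} or \code{"voxel"}.
#' @return non-negative scalar distance.
#' @export
min_boundary_distance <- function(a, b, voxel_size = a$voxel_size,
                                  units = c("um", "voxel")) {
  units <- match.arg(units)
  stopifnot(inherits(a, "spatial_object"), inherits(b, "spatial_object"))
  if (length(intersect(a$voxels, b$voxels)) > 0L) return(0)
  s <- if (units == "um") voxel_size else c(1, 1, 1)
  pa <- arrayInd(a$boundary, a$dim)
  pb <- arrayInd(b$boundary, b$dim)
  min(sqrt(outer(pa[, 1] * s[1], pb[, 1] * s[1], "-")^2 +
           outer(pa[, 2] * s[2], pb[, 2] * s[2], "-")^2 +
           outer(pa[, 3] * s[3], pb[, 3] * s[3], "-")^2))
}

#' ERES-LD association fraction
#'
#' For every ERES object, the closest boundary distance to any LD object;
#' the association fraction is the number of ERES with zero closest distance
#' (overlapping voxel sets) over the total number of ERES. With no LDs all
#' distances are \code{Inf} and the fraction is 0; with no ERES the fraction
#' is undefined (\code{NA}).
#'
#' @param eres,lds lists of \code{spatial_object}s (size-filter already
#'   applied by [segment_objects_3d()]).
#' @param voxel_size physical voxel dimensions \code{c(z, y, x)}, um.
#' @param units distance units, see [min_boundary_distance()].
#' @param adjacency_counts_as_zero also count ERES whose boundaries are
#'   26-adjacent to an LD (voxel-space distance <= sqrt(3)) as associated;
#'   off by default (association requires overlap).
#' @return list with \code{fraction} and data.frame \code{distances}
#'   (\code{eres}, \code{nearest_ld}, \code{distance}).
#' @export
eres_ld_association <- function(eres, lds, voxel_size = c(0.3, 0.065, 0.065),
                                units = "um", adjacency_counts_as_zero = FALSE) {
  if (length(eres) == 0L)
    return(list(fraction = NA_real_,
                distances = data.frame(eres = integer(0), nearest_ld = integer(0),
                                       distance = numeric(0))))
  rows <- lapply(seq_along(eres), function(i) {
    if (length(lds) == 0L)
      return(data.frame(eres = eres[[i]]$label, nearest_ld = NA_integer_,
                        distance = Inf, distance_vox = Inf))
    dv <- vapply(lds, function(l)
      min_boundary_distance(eres[[i]], l, voxel_size, units = "voxel"), 1)
    du <- if (units == "voxel") dv else vapply(lds, function(l)
      min_boundary_distance(eres[[i]], l, voxel_size, units = "um"), 1)
    j <- which.min(dv)
    data.frame(eres = eres[[i]]$label, nearest_ld = lds[[j]]$label,
               distance = du[j], distance_vox = dv[j])
  })
  tab <- do.call(rbind, rows)
  assoc <- tab$distance_vox == 0
  if (adjacency_counts_as_zero)
    assoc <- assoc | tab$distance_vox <= sqrt(3) + 1e-9
  list(fraction = mean(assoc),
       distances = tab[, c("eres", "nearest_ld", "distance")])
}

#' Pixel-intensity Pearson colocalization
#'
#' Pearson correlation of paired pixel/voxel intensities of two channels
#' within a region of interest.
#'
#' @param channel1,channel2 numeric arrays of identical shape.
#' @param roi optional binary mask of the same shape (default: everything).
#' @return correlation coefficient in \code{[-1, 1]}.
#' @export
pearson_colocalization <- function(channel1, channel2, roi = NULL) {
  if (!identical(dim(channel1), dim(channel2))) stopf("channel shapes differ")
  sel <- if (is.null(roi)) rep(TRUE, length(channel1)) else {
    if (!identical(dim(roi), dim(channel1))) stopf("roi shape differs")
    as.logical(roi)
  }
  v1 <- channel1[sel]; v2 <- channel2[sel]
  if (length(v1) < 2L) stopf("need >= 2 pixels in roi")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stopf("zero variance in roi; correlation undefined")
  stats::cor(v1, v2)
}
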