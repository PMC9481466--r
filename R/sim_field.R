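## Synthetic fluorescence fields --------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic screen imager. A field carries three channels
#' (protein / nuclei / LD stain, emulating FITC / Cy5 / DAPI). Cells are
#' rendered as smooth perturbed disks, nuclei as interior disks, lipid
#' droplets as small disks with rim-weighted protein signal; the protein
#' channel is built so that, on the ground-truth masks, the mean intensity
#' inside the LD mask divided by the mean outside (within the cell) equals
#' each cell's true targeting ratio exactly before optics and noise.
#' Acquisition is modelled as Gaussian PSF blur followed by Poisson shot
#' noise on the scaled signal plus additive Gaussian read noise; plate
#' autofluorescence is a constant additive offset on the protein channel.
#'
#' @param image_size field side in pixels (square field).
#' @param pixel_size_um pixel size in micrometres.
#' @param z_step_um z spacing for volumes, micrometres.
#' @param cells_per_field expected number of cells per field.
#' @param cell_radius_range min/max cell radius, px.
#' @param cell_irregularity amplitude of the low-order radial perturbation
#'   of the cell outline (0 = perfect disks).
#' @param nucleus_radius_frac nucleus radius as a fraction of cell radius.
#' @param lds_per_cell expected LD count per cell (Poisson).
#' @param ld_radius_range min/max LD radius, px.
#' @param ld_gap_px minimum edge-to-edge spacing between LDs of one cell, px.
#' @param rim_boost relative intensity excess of LD rim pixels over the LD
#'   interior in the protein channel (monolayer-surface localization).
#' @param protein_level mean protein-channel intensity outside LDs within an
#'   expressing cell, arbitrary camera units.
#' @param nucleus_level,ld_level marker-channel intensities on their objects.
#' @param cell_marker_level cytoplasmic intensity of the nuclear stain
#'   channel (far-red stains carry cell-body signal; this is what makes
#'   cell extent learnable from that channel).
#' @param background_level camera offset added to every channel.
#' @param autofluorescence_level additive plate autofluorescence on the
#'   protein channel.
#' @param psf_sigma Gaussian PSF standard deviation, px (0 = no blur).
#' @param poisson_scale photons per camera unit for shot noise
#'   (0 = no shot noise); relative noise at intensity I is
#'   \eqn{1/\sqrt{I \cdot \mathrm{scale}}}.
#' @param read_noise_sd additive Gaussian read noise sd (0 = none).
#' @param cell_ratio_cv lognormal cell-to-cell sd of the true targeting
#'   ratio around the well's value (median-preserving).
#' @param baseline_ratio true targeting ratio of a null (untreated) well.
#' @param n_fields fields imaged per well.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(image_size = 512L,
                       pixel_size_um = 0.065,
                       z_step_um = 0.3,
                       cells_per_field = 20L,
                       cell_radius_range = c(18, 26),
                       cell_irregularity = 0.12,
                       nucleus_radius_frac = 0.4,
                       lds_per_cell = 8,
                       ld_radius_range = c(3, 5),
                       ld_gap_px = 2,
                       rim_boost = 0.3,
                       protein_level = 400,
                       nucleus_level = 3000,
                       cell_marker_level = 600,
                       ld_level = 3000,
                       background_level = 100,
                       autofluorescence_level = 80,
                       psf_sigma = 0.3,
                       poisson_scale = 0.25,
                       read_noise_sd = 15,
                       cell_ratio_cv = 0.08,
                       baseline_ratio = 2.147287,
                       n_fields = 8L) {
  cfg <- list(image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
              z_step_um = z_step_um, cells_per_field = cells_per_field,
              cell_radius_range = cell_radius_range,
              cell_irregularity = cell_irregularity,
              nucleus_radius_frac = nucleus_radius_frac,
              lds_per_cell = lds_per_cell, ld_radius_range = ld_radius_range,
              ld_gap_px = ld_gap_px,
              rim_boost = rim_boost, protein_level = protein_level,
              nucleus_level = nucleus_level,
              cell_marker_level = cell_marker_level, ld_level = ld_level,
              background_level = background_level,
              autofluorescence_level = autofluorescence_level,
              psf_sigma = psf_sigma, poisson_scale = poisson_scale,
              read_noise_sd = read_noise_sd, cell_ratio_cv = cell_ratio_cv,
              baseline_ratio = baseline_ratio, n_fields = as.integer(n_fields))
  for (p in c("pixel_size_um", "z_step_um"))
    if (cfg[[p]] <= 0) stopf("%s must be > 0", p)
  for (p in c("psf_sigma", "poisson_scale", "read_noise_sd", "background_level",
              "autofluorescence_level", "cell_ratio_cv", "cell_irregularity"))
    if (cfg[[p]] < 0) stopf("%s must be >= 0", p)
  class(cfg) <- "sim_config"
  cfg
}

#' Ground-truth perturbation effect of a dsRNA
#'
#' @param dsrna_id reagent identifier (optional).
#' @param true_ratio expected per-cell LD targeting ratio (> 0).
#' @param cell_count_multiplier multiplier on cells per field (> 0);
#'   values well below 1 emulate knockdowns causing cell death.
#' @param ld_area_multiplier multiplier on LD area (> 0); values well below
#'   1 emulate knockdowns producing extremely small LDs.
#' @return list of class \code{gt_effect}.
#' @export
ground_truth_effect <- function(dsrna_id = NA_character_, true_ratio = 2.147287,
                                cell_count_multiplier = 1,
                                ld_area_multiplier = 1) {
  if (!is.finite(true_ratio) || true_ratio <= 0)
    stopf("true_ratio must be finite and > 0")
  if (!is.finite(cell_count_multiplier) || cell_count_multiplier <= 0 ||
      !is.finite(ld_area_multiplier) || ld_area_multiplier <= 0)
    stopf("effect multipliers must be finite and > 0")
  structure(list(dsrna_id = dsrna_id, true_ratio = true_ratio,
                 cell_count_multiplier = cell_count_multiplier,
                 ld_area_multiplier = ld_area_multiplier),
            class = "gt_effect")
}

## Gaussian smoothing by separable sampled kernel; replicate boundary.
gauss_filter <- function(x, sigma) {
  if (sigma <= 0) return(x)
  size <- 2L * ceiling(3 * sigma) + 1L
  ## truncate the kernel on images smaller than the nominal support
  fit <- 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L
  size <- min(size, fit)
  if (size < 3L) return(x)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(x, brush, boundary = "replicate"))
}

## 8-neighbour rim of a binary mask (pixels with >=1 background neighbour).
mask_rim <- function(mask) {
  mask <- as_mask(mask)
  er <- as.matrix(EBImage::erode(EBImage::Image(mask * 1),
                                 EBImage::makeBrush(3, "box"))) > 0
  mask & !er
}

#' Simulate one multi-channel field with ground truth
#'
#' Renders a field of cells according to a [ground_truth_effect()] and a
#' [sim_config()], returning the noisy three-channel image together with the
#' ground-truth label masks and per-cell true ratios. The same (inputs, seed)
#' always yields bit-identical output.
#'
#' @param effect a [ground_truth_effect()].
#' @param cfg a [sim_config()].
#' @param seed integer seed for this field.
#' @param role well role; for \code{"autofluorescence_control"} the cells
#'   express no protein, so the protein channel carries only
#'   autofluorescence, background and noise.
#' @return list with elements \code{image} (class \code{field_image}:
#'   matrices \code{protein}, \code{nuclei}, \code{ld}, plus
#'   \code{pixel_size_um}) and \code{truth} (class \code{field_truth}:
#'   label masks \code{nuclei}, \code{cells}, \code{lds}; named vector
#'   \code{cell_ratio} mapping cell label to its true ratio; integer vector
#'   \code{ld_cell} mapping LD label to owner cell).
#' @export
simulate_field <- function(effect, cfg = sim_config(), seed = 1L,
                           role = "library") {
  stopifnot(inherits(effect, "gt_effect"), inherits(cfg, "sim_config"))
  n <- cfg$image_size
  with_seed(seed, {
    n_cells <- round(cfg$cells_per_field * effect$cell_count_multiplier)
    L <- matrix(0L, n, n)          # cell labels
    score <- matrix(Inf, n, n)     # normalized radial coordinate, for overlaps
    nuc <- matrix(0L, n, n)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    if (n_cells > 0) {
      rmin <- cfg$cell_radius_range[1]; rmax <- cfg$cell_radius_range[2]
      tries <- 0L
      while (nrow(centers) < n_cells && tries < 400L * n_cells) {
        tries <- tries + 1L
        R <- runif(1, rmin, rmax)
        cy <- runif(1, R * 0.3, n - R * 0.3)  # cells may touch the border
        cx <- runif(1, R * 0.3, n - R * 0.3)
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          if (any(d < 0.95 * (radii + R))) next
        }
        centers <- rbind(centers, c(cy, cx)); radii <- c(radii, R)
      }
      for (i in seq_len(nrow(centers))) {
        R <- radii[i]; cy <- centers[i, 1]; cx <- centers[i, 2]
        amp <- cfg$cell_irregularity * runif(3) / (2:4)
        phs <- runif(3, 0, 2 * pi)
        ext <- ceiling(R * (1 + sum(amp)))
        ys <- max(1L, floor(cy - ext)):min(n, ceiling(cy + ext))
        xs <- max(1L, floor(cx - ext)):min(n, ceiling(cx + ext))
        dy <- outer(ys - cy, rep(1, length(xs)))
        dx <- outer(rep(1, length(ys)), xs - cx)
        d <- sqrt(dy^2 + dx^2)
        th <- atan2(dy, dx)
        rad <- R * (1 + amp[1] * cos(2 * th + phs[1]) +
                        amp[2] * cos(3 * th + phs[2]) +
                        amp[3] * cos(4 * th + phs[3]))
        s <- d / rad
        sub_s <- score[ys, xs]; sub_l <- L[ys, xs]
        sel <- s <= 1 & s < sub_s
        sub_s[sel] <- s[sel]; sub_l[sel] <- i
        score[ys, xs] <- sub_s; L[ys, xs] <- sub_l
        ## nucleus: interior disk, clipped to this cell's pixels
        nr <- cfg$nucleus_radius_frac * R
        nsel <- d <= nr & L[ys, xs] == i
        sub_n <- nuc[ys, xs]; sub_n[nsel] <- i; nuc[ys, xs] <- sub_n
      }
    }
    ## lipid droplets
    ld <- matrix(0L, n, n)
    ld_cell <- integer(0)
    next_ld <- 0L
    cell_labels <- if (nrow(centers) > 0) seq_len(nrow(centers)) else integer(0)
    for (i in cell_labels) {
      cyto <- which(L == i & nuc == 0L & ld == 0L)
      m <- rpois(1, cfg$lds_per_cell)
      if (m == 0L || length(cyto) == 0L) next
      rr <- runif(m, cfg$ld_radius_range[1], cfg$ld_radius_range[2]) *
        sqrt(effect$ld_area_multiplier)
      ## LDs are distinct puncta: keep centres separated so objects do not
      ## touch (placements that do not fit are dropped)
      placed <- matrix(numeric(0), 0, 2)
      placed_r <- numeric(0)
      cand <- sample(cyto, min(8L * m, length(cyto)), replace = FALSE)
      ctr <- integer(0)
      for (cj in cand) {
        if (length(ctr) >= m) break
        ci <- arrayInd(cj, c(n, n))
        r_new <- rr[length(ctr) + 1L]
        if (nrow(placed) > 0L) {
          dd <- sqrt((placed[, 1] - ci[1])^2 + (placed[, 2] - ci[2])^2)
          if (any(dd < placed_r + r_new + cfg$ld_gap_px)) next
        }
        placed <- rbind(placed, ci); placed_r <- c(placed_r, r_new)
        ctr <- c(ctr, cj)
      }
      for (j in seq_along(ctr)) {
        ci <- arrayInd(ctr[j], c(n, n))
        ext <- ceiling(rr[j])
        ys <- max(1L, ci[1] - ext):min(n, ci[1] + ext)
        xs <- max(1L, ci[2] - ext):min(n, ci[2] + ext)
        d <- sqrt(outer((ys - ci[1])^2, rep(1, length(xs))) +
                  outer(rep(1, length(ys)), (xs - ci[2])^2))
        sel <- d <= rr[j] & L[ys, xs] == i & nuc[ys, xs] == 0L & ld[ys, xs] == 0L
        if (!any(sel)) next
        next_ld <- next_ld + 1L
        sub <- ld[ys, xs]; sub[sel] <- next_ld; ld[ys, xs] <- sub
        ld_cell[next_ld] <- i
      }
    }
    if (next_ld > 0L) names(ld_cell) <- as.character(seq_len(next_ld))

    ## per-cell true ratios (median-preserving lognormal spread)
    cell_ratio <- stats::setNames(
      effect$true_ratio * exp(rnorm(length(cell_labels), 0, cfg$cell_ratio_cv)),
      as.character(cell_labels))

    ## clean channels
    P <- matrix(0, n, n)
    expressing <- !identical(role, "autofluorescence_control")
    if (expressing) {
      rim <- mask_rim(ld > 0L)
      for (i in cell_labels) {
        in_cell <- L == i
        ld_px <- which(in_cell & ld > 0L)
        out_px <- which(in_cell & ld == 0L)
        P[out_px] <- cfg$protein_level
        if (length(ld_px) > 0L) {
          ## reticular pool contributes uniformly; only the LD-targeted
          ## excess (r - 1) is rim-weighted. Mean over the cell's LD pixels
          ## is exactly r * out level.
          w <- 1 + cfg$rim_boost * rim[ld_px]
          r_i <- cell_ratio[[as.character(i)]]
          P[ld_px] <- cfg$protein_level +
            (r_i - 1) * cfg$protein_level * w * length(ld_px) / sum(w)
        }
      }
    }
    prot <- P + cfg$autofluorescence_level + cfg$background_level
    nucch <- cfg$nucleus_level * (nuc > 0L) +
      cfg$cell_marker_level * (L > 0L & nuc == 0L) + cfg$background_level
    ldch <- cfg$ld_level * (ld > 0L) + cfg$background_level

    channels <- list(protein = prot, nuclei = nucch, ld = ldch)
    if (cfg$psf_sigma > 0)
      channels <- lapply(channels, gauss_filter, sigma = cfg$psf_sigma)
    if (cfg$poisson_scale > 0)
      channels <- lapply(channels, function(x) {
        matrix(rpois(length(x), pmax(x, 0) * cfg$poisson_scale) /
                 cfg$poisson_scale, n, n)
      })
    if (cfg$read_noise_sd > 0)
      channels <- lapply(channels, function(x)
        pmax(x + matrix(rnorm(length(x), 0, cfg$read_noise_sd), n, n), 0))

    image <- structure(c(channels, list(pixel_size_um = cfg$pixel_size_um)),
                       class = "field_image")
    truth <- structure(list(nuclei = nuc, cells = L, lds = ld,
                            cell_ratio = cell_ratio, ld_cell = ld_cell),
                       class = "field_truth")
    list(image = image, truth = truth)
  })
}

#' Simulate all fields of one well
#'
#' Field seeds are derived deterministically from (plate, well, field index,
#' master seed) with [derive_seed()], so any field can be regenerated in
#' isolation.
#'
#' @inheritParams simulate_field
#' @param well well coordinate, e.g. \code{"A01"}.
#' @param plate plate identifier.
#' @param n_fields number of fields (default from \code{cfg}, screen standard 8).
#' @param seed master seed.
#' @return list of \code{n_fields} results of [simulate_field()].
#' @export
simulate_well <- function(well, effect, cfg = sim_config(), n_fields = cfg$n_fields,
                          seed = 1L, plate = 1L, role = "library") {
  stopifnot(n_fields >= 1L)
  lapply(seq_len(n_fields), function(f)
    simulate_field(effect, cfg, seed = derive_seed(seed, plate, well, f),
                   role = role))
}
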