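## Synthetic 3D volumes for ERES-LD association ------------------------------

## boundary voxels of a voxel index set: >=1 of the 26 neighbours outside the
## set (or outside the volume)
boundary_of <- function(vox, d) {
  inset <- array(FALSE, d); inset[vox] <- TRUE
  idx <- arrayInd(vox, d)
  isb <- rep(FALSE, length(vox))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    z <- idx[, 1] + dz; y <- idx[, 2] + dy; x <- idx[, 3] + dx
    out <- z < 1L | z > d[1] | y < 1L | y > d[2] | x < 1L | x > d[3]
    lin <- (pmax(x, 1L) - 1L) * d[1] * d[2] + (pmax(y, 1L) - 1L) * d[1] + pmax(z, 1L)
    isb <- isb | out | !inset[lin]
  }
  vox[isb]
}

## brute-force minimum boundary-to-boundary distance in voxel units (0 if the
## voxel sets share a voxel); used to certify ground-truth placements
bf_boundary_dist <- function(voxA, voxB, d) {
  if (length(intersect(voxA, voxB)) > 0L) return(0)
  ba <- arrayInd(boundary_of(voxA, d), d)
  bb <- arrayInd(boundary_of(voxB, d), d)
  min(sqrt(outer(ba[, 1], bb[, 1], "-")^2 +
           outer(ba[, 2], bb[, 2], "-")^2 +
           outer(ba[, 3], bb[, 3], "-")^2))
}

sphere_voxels <- function(center, radius, d) {
  if (any(!is.finite(center))) return(integer(0))
  ext <- ceiling(radius)
  rng <- function(c, n) {
    lo <- max(1L, floor(c - ext)); hi <- min(n, ceiling(c + ext))
    if (lo > hi) integer(0) else lo:hi
  }
  zs <- rng(center[1], d[1]); ys <- rng(center[2], d[2]); xs <- rng(center[3], d[3])
  if (!length(zs) || !length(ys) || !length(xs)) return(integer(0))
  g <- expand.grid(z = zs, y = ys, x = xs)
  g <- g[(g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <=
           radius^2, , drop = FALSE]
  (g$x - 1L) * d[1] * d[2] + (g$y - 1L) * d[1] + g$z
}

#' Simulate a two-channel 3D volume with ERES and LD objects
#'
#' Places LD spheres at random, then one ERES punctum per row of
#' \code{eres_spec} at a requested boundary distance from the nearest LD
#' (voxel units; 0 means overlapping voxel sets). Each placement is certified
#' by exhaustive boundary-distance computation and accepted only within half
#' a voxel of the request; unsatisfiable placements error after bounded
#' retries. Channels get the same blur/noise model as 2D fields (PSF applied
#' per z-slice; the coarse z step is not blurred).
#'
#' @param cfg a [sim_config()] (levels, background, noise, voxel sizes).
#' @param eres_spec two-column matrix or data.frame: target ERES size in
#'   voxels and requested boundary distance to the nearest LD in voxels.
#'   Zero rows mean no ERES objects.
#' @param seed integer seed.
#' @param dim volume dimensions \code{c(z, y, x)}.
#' @param n_lds number of LD spheres.
#' @param ld_radius_range LD sphere radius range, voxels.
#' @return list with \code{volume} (class \code{volume_image}: arrays
#'   \code{eres} and \code{ld} in (z, y, x) order plus
#'   \code{voxel_size_um = c(z, y, x)}) and \code{truth} (label arrays
#'   \code{eres}, \code{lds}; \code{eres_distance}: certified ground-truth
#'   boundary distance of each ERES to its nearest LD, voxel units;
#'   \code{eres_size}: realized voxel counts).
#' @export
simulate_volume <- function(cfg = sim_config(), eres_spec, seed = 1L,
                            dim = c(24L, 96L, 96L), n_lds = 5L,
                            ld_radius_range = c(3, 6)) {
  eres_spec <- as.matrix(eres_spec)
  if (ncol(eres_spec) == 0L) eres_spec <- matrix(numeric(0), 0, 2)
  stopifnot(ncol(eres_spec) == 2L || nrow(eres_spec) == 0L)
  if (nrow(eres_spec) > 0L) {
    if (any(eres_spec[, 1] < 1)) stopf("ERES sizes must be >= 1 voxel")
    if (any(eres_spec[, 2] < 0)) stopf("requested distances must be >= 0")
  }
  d <- as.integer(dim)
  with_seed(seed, {
    ld_lab <- array(0L, d)
    ld_vox <- list()
    margin <- pmin(max(ld_radius_range) + 2, (d - 1) / 2)
    for (i in seq_len(n_lds)) {
      for (try in 1:200) {
        ctr <- c(runif(1, margin[1], d[1] - margin[1]),
                 runif(1, margin[2], d[2] - margin[2]),
                 runif(1, margin[3], d[3] - margin[3]))
        r <- runif(1, ld_radius_range[1], ld_radius_range[2])
        vox <- sphere_voxels(ctr, r, d)
        if (length(vox) > 0L && all(ld_lab[vox] == 0L)) {
          ld_lab[vox] <- i
          ld_vox[[i]] <- vox
          break
        }
        if (try == 200) stopf("could not place LD %d after bounded retries", i)
      }
    }
    ld_centers <- t(vapply(ld_vox, function(v) colMeans(arrayInd(v, d)), numeric(3)))

    er_lab <- array(0L, d)
    er_dist <- numeric(nrow(eres_spec))
    er_size <- integer(nrow(eres_spec))
    for (k in seq_len(nrow(eres_spec))) {
      size <- eres_spec[k, 1]; want <- eres_spec[k, 2]
      ## smallest lattice-sphere radius whose voxel count reaches the
      ## requested size (the continuum radius undercounts on the lattice)
      re <- max(1, (3 * size / (4 * pi))^(1 / 3))
      big <- c(64L, 64L, 64L)
      while (length(sphere_voxels(c(32, 32, 32), re, big)) < size) re <- re + 0.1
      placed <- FALSE
      for (try in 1:60) {
        i <- sample.int(n_lds, 1)
        if (want == 0) {
          ## centre on an LD boundary voxel: voxel sets share >=1 voxel
          bvox <- boundary_of(ld_vox[[i]], d)
          ctr <- as.numeric(arrayInd(sample(bvox, 1), d))
        } else {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          rld <- max(sqrt(rowSums((arrayInd(ld_vox[[i]], d) -
                     matrix(ld_centers[i, ], length(ld_vox[[i]]), 3, byrow = TRUE))^2)))
          ctr <- ld_centers[i, ] + u * (rld + want + re)
          ## refine along u against the certified distance
          for (ref in 1:8) {
            if (any(ctr < 1 + re) || any(ctr > d - re)) break
            vox <- sphere_voxels(ctr, re, d)
            if (length(vox) == 0L) break
            meas <- min(vapply(ld_vox, function(lv) bf_boundary_dist(vox, lv, d), 1))
            if (abs(meas - want) <= 0.5) break
            ctr <- ctr + u * (want - meas)
          }
        }
        if (any(ctr < 1) || any(ctr > d)) next
        vox <- sphere_voxels(ctr, re, d)
        vox <- vox[er_lab[vox] == 0L]
        if (want > 0) vox <- vox[ld_lab[vox] == 0L]
        ## reject placements clipped well below the requested size
        if (length(vox) < 0.8 * size) next
        ## keep distinct ERES objects from touching (26-adjacency merges them)
        if (max(er_lab) > 0L) {
          prev <- which(er_lab > 0L)
          pi <- arrayInd(prev, d); vi <- arrayInd(vox, d)
          mind <- min(sqrt(outer(pi[, 1], vi[, 1], "-")^2 +
                           outer(pi[, 2], vi[, 2], "-")^2 +
                           outer(pi[, 3], vi[, 3], "-")^2))
          if (mind <= sqrt(3) + 1e-9) next
        }
        meas <- min(vapply(ld_vox, function(lv) bf_boundary_dist(vox, lv, d), 1))
        if (abs(meas - want) <= 0.5) {
          er_lab[vox] <- k
          er_dist[k] <- meas
          er_size[k] <- length(vox)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("unsatisfiable ERES placement (size %g at distance %g) after bounded retries",
              size, want)
    }

    mk_channel <- function(lab, level) {
      x <- level * (lab > 0L) + cfg$background_level
      if (cfg$psf_sigma > 0)
        for (z in seq_len(d[1])) x[z, , ] <- gauss_filter(x[z, , ], cfg$psf_sigma)
      if (cfg$poisson_scale > 0)
        x <- array(rpois(length(x), pmax(x, 0) * cfg$poisson_scale) /
                     cfg$poisson_scale, d)
      if (cfg$read_noise_sd > 0)
        x <- pmax(x + array(rnorm(length(x), 0, cfg$read_noise_sd), d), 0)
      x
    }
    volume <- structure(list(eres = mk_channel(er_lab, cfg$ld_level),
                             ld = mk_channel(ld_lab, cfg$ld_level),
                             voxel_size_um = c(cfg$z_step_um, cfg$pixel_size_um,
                                               cfg$pixel_size_um)),
                        class = "volume_image")
    truth <- list(eres = er_lab, lds = ld_lab,
                  eres_distance = er_dist, eres_size = er_size)
    list(volume = volume, truth = truth)
  })
}
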