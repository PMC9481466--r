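#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so simulation never perturbs the
## session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a reproducible sub-seed from a master seed and context labels
#'
#' Stable 31-bit polynomial hash of the master seed together with arbitrary
#' string/number context (plate, well, field index, ...). Used so that every
#' simulated field gets its own RNG stream that depends only on its identity
#' and the master seed, never on evaluation order.
#'
#' @param seed master seed (integer).
#' @param ... context labels (coerced to character).
#' @return integer in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  m <- 2147483647
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_binary_mask <- function(x) {
  (is.logical(x) || all(x %in% c(0, 1))) && length(dim(x)) == 2L
}

as_mask <- function(x) {
  if (is.logical(x)) x else x > 0
}

## 8-connected labelling of a 2D binary mask. EBImage::bwlabel is
## 4-connected, so components that only touch diagonally are merged
## afterwards with a union-find pass over diagonal adjacencies.
label_components_2d <- function(mask) {
  mask <- as_mask(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## label pairs adjacent along the two diagonal directions
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, 1L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- dense[out[out > 0L]]
  out
}

## 26-connected labelling of a 3D binary array by vectorised multi-source
## flood fill. Adequate for the desk-scale volumes this package simulates.
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  mask <- array(as_mask(mask), d)
  lab <- array(0L, d)
  nvox <- prod(d)
  ## linear-index offsets of the 26 neighbours
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  todo <- which(mask & lab == 0L)
  nextlab <- 0L
  while (length(todo) > 0L) {
    nextlab <- nextlab + 1L
    frontier <- todo[1L]
    lab[frontier] <- nextlab
    while (length(frontier) > 0L) {
      idx <- arrayInd(frontier, d)
      nb <- integer(0)
      for (r in seq_len(nrow(offs))) {
        z <- idx[, 1] + offs[r, 1]; y <- idx[, 2] + offs[r, 2]; x <- idx[, 3] + offs[r, 3]
        ok <- z >= 1L & z <= d[1] & y >= 1L & y <= d[2] & x >= 1L & x <= d[3]
        if (any(ok)) nb <- c(nb, (x[ok] - 1L) * d[1] * d[2] + (y[ok] - 1L) * d[1] + z[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

## Relabel positive labels to contiguous 1..K (order preserved).
relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  out <- lab
  out[out > 0L] <- match(lab[lab > 0L], u)
  out
}
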