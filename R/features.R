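## Per-pixel feature bank for pixel classification ---------------------------

laplacian_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

#' Extract a per-pixel feature stack from one image channel
#'
#' Deterministic filter bank: raw intensity, Gaussian smoothings at several
#' scales, differences of Gaussians between consecutive scales, gradient
#' magnitude and Laplacian at the finest scale. This is the representation
#' the random-forest pixel classifiers are trained on.
#'
#' @param image 2D numeric matrix, non-negative intensities.
#' @param sigmas Gaussian scales in pixels.
#' @return array \code{nrow x ncol x n_features} with feature names in the
#'   third dimnames.
#' @export
extract_features <- function(image, sigmas = c(1, 2, 4)) {
  if (length(image) == 0L) stopf("empty image")
  if (length(dim(image)) != 2L) stopf("image must be a 2D matrix")
  image <- as.matrix(image)
  g <- lapply(sigmas, function(s) gauss_filter(image, s))
  gx <- (g[[1]][, c(2:ncol(image), ncol(image))] -
           g[[1]][, c(1, 1:(ncol(image) - 1))]) / 2
  gy <- (g[[1]][c(2:nrow(image), nrow(image)), ] -
           g[[1]][c(1, 1:(nrow(image) - 1)), ]) / 2
  feats <- c(list(raw = image),
             stats::setNames(g, sprintf("gauss_s%g", sigmas)),
             stats::setNames(
               lapply(seq_len(length(sigmas) - 1),
                      function(i) g[[i]] - g[[i + 1]]),
               sprintf("dog_s%g_s%g", sigmas[-length(sigmas)], sigmas[-1])),
             list(grad_mag = sqrt(gx^2 + gy^2),
                  laplacian = as.matrix(EBImage::filter2(g[[1]], laplacian_kernel,
                                                         boundary = "replicate"))))
  out <- array(unlist(feats, use.names = FALSE),
               dim = c(nrow(image), ncol(image), length(feats)),
               dimnames = list(NULL, NULL, names(feats)))
  out
}

feature_matrix <- function(stack, idx = NULL) {
  n <- prod(dim(stack)[1:2])
  m <- matrix(stack, nrow = n, ncol = dim(stack)[3],
              dimnames = list(NULL, dimnames(stack)[[3]]))
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}
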