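## Random-forest pixel classifiers ------------------------------------------

#' Train a random-forest pixel classifier for one compartment
#'
#' One model per compartment (nucleus / cell / LD), following the screen's
#' design of three separately trained classifiers on small sets of annotated
#' images. Pixels are sampled class-balanced from the annotations, features
#' come from [extract_features()], and the forest is a
#' \code{\link[ranger]{ranger}} probability forest with a fixed seed. The
#' out-of-bag classification accuracy is stored as the held-out accuracy
#' estimate.
#'
#' @param annotated list of \code{list(image =, labels =)} pairs; labels are
#'   integer matrices of the image's shape with 0 = unannotated,
#'   1 = background, 2 = foreground (higher classes allowed; the largest
#'   class is taken as foreground).
#' @param compartment one of \code{"nucleus"}, \code{"cell"}, \code{"ld"}.
#' @param seed RNG seed for sampling and forest growth.
#' @param n_trees forest size.
#' @param pixels_per_class maximum training pixels per class per image.
#' @param sigmas feature scales, stored with the model.
#' @return object of class \code{pixel_classifier}.
#' @export
train_pixel_classifier <- function(annotated,
                                   compartment = c("nucleus", "cell", "ld"),
                                   seed = 1L, n_trees = 100L,
                                   pixels_per_class = 2000L,
                                   sigmas = c(1, 2, 4)) {
  compartment <- match.arg(compartment)
  if (length(annotated) < 1L) stopf("need at least one annotated image")
  with_seed(seed, {
    xs <- list(); ys <- list()
    for (k in seq_along(annotated)) {
      img <- annotated[[k]]$image; lab <- annotated[[k]]$labels
      if (is.null(img) || is.null(lab))
        stopf("annotated[[%d]] must have 'image' and 'labels'", k)
      if (!identical(dim(img), dim(lab)))
        stopf("annotated[[%d]]: labels shape %s does not match image shape %s",
              k, paste(dim(lab), collapse = "x"), paste(dim(img), collapse = "x"))
      stack <- extract_features(img, sigmas)
      for (cl in sort(unique(lab[lab > 0L]))) {
        idx <- which(lab == cl)
        if (length(idx) > pixels_per_class)
          idx <- sample(idx, pixels_per_class)
        xs[[length(xs) + 1L]] <- feature_matrix(stack, idx)
        ys[[length(ys) + 1L]] <- rep(cl, length(idx))
      }
    }
    y <- unlist(ys)
    classes <- sort(unique(y))
    if (length(classes) < 2L)
      stopf("annotations contain a single class (%s); need >= 2", classes[1])
    x <- do.call(rbind, xs)
    dat <- data.frame(x, .class = factor(y, levels = classes))
    fit <- ranger::ranger(.class ~ ., data = dat, num.trees = n_trees,
                          probability = TRUE, seed = seed,
                          num.threads = 1L)
    oob_class <- classes[max.col(fit$predictions, ties.method = "first")]
    structure(list(forest = fit, compartment = compartment, sigmas = sigmas,
                   feature_names = colnames(x),
                   foreground_class = max(classes),
                   meta = list(n_images = length(annotated), seed = seed,
                               n_trees = n_trees,
                               oob_accuracy = mean(oob_class == y))),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("Pixel classifier [%s]: %d trees, %d images, OOB accuracy %.3f\n",
              x$compartment, x$meta$n_trees, x$meta$n_images,
              x$meta$oob_accuracy))
  invisible(x)
}

#' Classify pixels of a channel into a binary foreground mask
#'
#' @param model a [train_pixel_classifier()] model.
#' @param image 2D matrix of the channel the model was trained on.
#' @param prob_threshold foreground is where the predicted foreground-class
#'   probability is at least this value (default 0.5).
#' @return logical matrix of the image's shape.
#' @export
classify_pixels <- function(model, image, prob_threshold = 0.5) {
  if (!inherits(model, "pixel_classifier")) stopf("not a pixel_classifier")
  stack <- extract_features(image, model$sigmas)
  fm <- feature_matrix(stack)
  if (!identical(colnames(fm), model$feature_names))
    stopf("feature descriptor mismatch between model and image")
  pr <- stats::predict(model$forest, data.frame(fm), num.threads = 1L)$predictions
  fg <- pr[, as.character(model$foreground_class)]
  matrix(fg >= prob_threshold, nrow(image), ncol(image))
}

#' Foreground probability map (no thresholding)
#'
#' Used as the watershed relief for cell segmentation.
#' @inheritParams classify_pixels
#' @return numeric matrix of foreground probabilities in \code{[0, 1]}.
#' @export
pixel_probability <- function(model, image) {
  if (!inherits(model, "pixel_classifier")) stopf("not a pixel_classifier")
  stack <- extract_features(image, model$sigmas)
  fm <- feature_matrix(stack)
  pr <- stats::predict(model$forest, data.frame(fm), num.threads = 1L)$predictions
  matrix(pr[, as.character(model$foreground_class)], nrow(image), ncol(image))
}
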