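#' Fit the LDA nuclei model
#'
#' Cell nuclei have negative contrast in all three multimodal channels, so a
#' two-class linear discriminant on the raw (CARS, TPEF, SHG) intensity
#' triplet separates nucleus from non-nucleus pixels. The model uses the
#' classic pooled-covariance form: with class means `mu0`, `mu1`, pooled
#' covariance `S` and priors `pi0`, `pi1`, the posterior probability of
#' "nucleus" is the logistic of the affine discriminant
#' `w'x + b`, `w = S^-1 (mu1 - mu0)`,
#' `b = -(mu0 + mu1)' w / 2 + log(pi1 / pi0)`.
#' A singular pooled covariance is ridge-regularised by adding
#' `eps * trace(S) / 3` to the diagonal (with a warning).
#'
#' @param pixels numeric matrix `n x 3` of channel intensities.
#' @param labels logical (or coercible) vector, `TRUE` = nucleus; at least
#'   10 samples per class.
#' @param threshold posterior-probability decision threshold (default 0.5).
#' @param min_area minimum connected-component area (pixels) kept in
#'   predicted masks (default 5).
#' @param ridge_eps ridge fraction used when the covariance is singular.
#' @return An object of class `nuclei_model`.
#' @export
fit_nuclei_model <- function(pixels, labels, threshold = 0.5, min_area = 5L,
                             ridge_eps = 1e-6) {
  pixels <- as.matrix(pixels)
  labels <- as.logical(labels)
  if (ncol(pixels) != 3L) stop("`pixels` must have 3 columns")
  if (length(labels) != nrow(pixels)) stop("label length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n0 < 10 || n1 < 10)
    stop("need at least 10 samples in each class (nucleus / not-nucleus)")
  mu0 <- colMeans(pixels[!labels, , drop = FALSE])
  mu1 <- colMeans(pixels[labels, , drop = FALSE])
  S0 <- cov(pixels[!labels, , drop = FALSE])
  S1 <- cov(pixels[labels, , drop = FALSE])
  S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond(S) < 1e-12) {
    warning("singular pooled covariance: ridge-regularising")
    S <- S + diag(ridge_eps * sum(diag(S)) / 3 + 1e-12, 3)
    w <- solve(S, mu1 - mu0)
  }
  prior1 <- n1 / (n0 + n1)
  b <- -sum((mu0 + mu1) * w) / 2 + log(prior1 / (1 - prior1))
  structure(
    list(mu0 = mu0, mu1 = mu1, cov = S, w = w, b = b, prior1 = prior1,
         threshold = threshold, min_area = as.integer(min_area),
         trained = TRUE),
    class = "nuclei_model"
  )
}

#' Calibrate the nuclei decision threshold on labelled pixels
#'
#' The 0.5 posterior threshold is optimal for pixel-wise error under the
#' LDA model, but mask quality is better measured by overlap: this scans
#' candidate thresholds (posterior quantiles of the supplied pixels) and
#' stores the one maximising the intersection-over-union between the
#' thresholded mask and the labels. Calibration uses training data only.
#'
#' @param model a [fit_nuclei_model()] result.
#' @param pixels numeric matrix `n x 3` of labelled pixels.
#' @param labels logical, `TRUE` = nucleus.
#' @param n_grid number of candidate thresholds.
#' @return The model with an updated `threshold`.
#' @export
calibrate_nuclei_threshold <- function(model, pixels, labels, n_grid = 41L) {
  stopifnot(inherits(model, "nuclei_model"))
  labels <- as.logical(labels)
  post <- nuclei_posterior(model, pixels)
  cand <- unique(quantile(post, seq(0.02, 0.98, length.out = n_grid),
                          names = FALSE))
  iou <- vapply(cand, function(th) {
    pred <- post >= th
    u <- sum(pred | labels)
    if (u == 0) 0 else sum(pred & labels) / u
  }, numeric(1))
  model$threshold <- cand[which.max(iou)]
  model
}

#' Posterior probability of "nucleus" for pixel intensity triplets
#' @param model a [fit_nuclei_model()] result.
#' @param pixels numeric matrix `n x 3`.
#' @return Numeric vector of posterior probabilities.
#' @export
nuclei_posterior <- function(model, pixels) {
  stopifnot(inherits(model, "nuclei_model"))
  plogis(drop(as.matrix(pixels) %*% model$w) + model$b)
}

#' Predict the nuclei mask of a multimodal image
#'
#' Pixel-wise posterior thresholding followed by removal of connected
#' components smaller than `min_area` (the region-scale cleanup standing in
#' for region-level prediction).
#'
#' @param model a [fit_nuclei_model()] result.
#' @param mm a [multimodal_image].
#' @param threshold,min_area optional overrides of the stored values.
#' @return A logical matrix, `TRUE` = nucleus.
#' @export
predict_nuclei_mask <- function(model, mm, threshold = NULL, min_area = NULL) {
  stopifnot(inherits(mm, "multimodal_image"))
  if (!inherits(model, "nuclei_model") || !isTRUE(model$trained))
    stop("`model` is not a trained nuclei_model")
  threshold <- if (is.null(threshold)) model$threshold else threshold
  min_area <- if (is.null(min_area)) model$min_area else min_area
  d <- dim(mm$channels)
  post <- matrix(nuclei_posterior(model, mm_pixels(mm)), d[1], d[2])
  ## the posterior is strictly below 1, but plogis saturates in floating
  ## point; threshold >= 1 therefore means "no pixel qualifies"
  mask <- if (threshold >= 1) matrix(FALSE, d[1], d[2]) else post >= threshold
  if (min_area > 1 && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_area)
    mask <- matrix(as.integer(lab) %in% keep, d[1], d[2]) & mask
  }
  mask
}

#' @export
print.nuclei_model <- function(x, ...) {
  cat("<nuclei_model> two-class LDA on CARS/TPEF/SHG;",
      "threshold", x$threshold, "min_area", x$min_area, "\n")
  invisible(x)
}
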