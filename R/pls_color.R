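#' Fit the PLS colour model mapping multimodal channels to HE RGB
#'
#' Trains a multivariate partial least squares regression (PLS2, NIPALS) of
#' the HE RGB values on the three multimodal channel intensities over the
#' selected training pixels. With 3 components on full-rank inputs the
#' predictor coincides with the ordinary least squares fit; fewer components
#' give a regularised (reduced-rank) colour map. A single joint PLS2 model
#' is used for all three outputs rather than three separate fits, so
#' response covariance informs the latent directions.
#'
#' @param mm a [multimodal_image], pixel-registered with `he`.
#' @param he RGB array `rows x cols x 3` (the HE reference stain).
#' @param n_components number of latent components, 1 to 3 (default 3).
#' @param mask optional logical matrix selecting training pixels (e.g.
#'   foreground only); default uses every pixel.
#' @return An object of class `color_model` with the affine predictor
#'   (`x_mean`, `y_mean`, `coef`), the per-component weights and loadings,
#'   and the training RMSE.
#' @export
fit_color_model <- function(mm, he, n_components = 3L, mask = NULL) {
  stopifnot(inherits(mm, "multimodal_image"))
  d <- dim(mm$channels)
  if (!identical(dim(he), d))
    stop("`mm` and `he` must be pixel-registered with identical shapes")
  if (!n_components %in% 1:3) stop("`n_components` must be 1, 2 or 3")
  X <- mm_pixels(mm)
  Y <- matrix(he, d[1] * d[2], 3, dimnames = list(NULL, c("R", "G", "B")))
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) stop("mask shape mismatch")
    X <- X[as.vector(mask), , drop = FALSE]
    Y <- Y[as.vector(mask), , drop = FALSE]
  }
  fit <- pls2_nipals(X, Y, n_components)
  fit$trained <- TRUE
  class(fit) <- "color_model"
  fit
}

## NIPALS PLS2 with X-deflation; coefficients via B = W (P'W)^-1 Q with Q
## the regression of centred Y on the (orthogonal) score matrix T.
pls2_nipals <- function(X, Y, a, tol = 1e-12, max_iter = 500L) {
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  Xr <- Xc
  n <- nrow(X); px <- ncol(X); py <- ncol(Y)
  W <- matrix(0, px, a); P <- matrix(0, px, a); Tm <- matrix(0, n, a)
  used <- 0L
  xscale <- sqrt(sum(Xc^2)) + .Machine$double.eps
  for (comp in seq_len(a)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(0, n)
    w <- NULL; tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xr, u))
      nw <- sqrt(sum(w^2))
      if (nw < tol * xscale) { w <- NULL; break }
      w <- w / nw
      tt <- drop(Xr %*% w)
      st <- sum(tt^2)
      if (st < (tol * xscale)^2) { w <- NULL; break }
      cc <- drop(crossprod(Yc, tt)) / st
      sc <- sum(cc^2)
      if (sc < tol^2) break               # Y exhausted; keep component
      u_new <- drop(Yc %*% cc) / sc
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(st)) { u <- u_new; break }
      t_old <- tt; u <- u_new
    }
    if (is.null(w)) {
      warning("rank-deficient inputs: reduced to ", used, " PLS component(s)")
      break
    }
    p <- drop(crossprod(Xr, tt)) / sum(tt^2)
    Xr <- Xr - tcrossprod(tt, p)
    used <- used + 1L
    W[, used] <- w; P[, used] <- p; Tm[, used] <- tt
  }
  if (used == 0L) stop("no usable PLS component: X has no variance")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Tm <- Tm[, seq_len(used), drop = FALSE]
  Q <- solve(crossprod(Tm), crossprod(Tm, Yc))       # used x py
  B <- W %*% solve(crossprod(P, W), Q)               # px x py
  fitted <- sweep(Xc %*% B, 2, y_mean, "+")
  rmse <- sqrt(mean((fitted - Y)^2))
  list(x_mean = x_mean, y_mean = y_mean, coef = B,
       weights = W, loadings = P, n_components = used, rmse = rmse)
}

#' Predict pseudo-HE colours from a multimodal image
#'
#' Applies the trained affine colour predictor pixel-wise and clips the
#' result to `[0, 1]`.
#'
#' @param model a [fit_color_model()] result.
#' @param mm a [multimodal_image].
#' @return RGB array `rows x cols x 3` in `[0, 1]`.
#' @export
predict_color <- function(model, mm) {
  stopifnot(inherits(mm, "multimodal_image"))
  if (!inherits(model, "color_model") || !isTRUE(model$trained))
    stop("`model` is not a trained color_model")
  d <- dim(mm$channels)
  X <- mm_pixels(mm)
  pred <- sweep(sweep(X, 2, model$x_mean) %*% model$coef, 2, model$y_mean, "+")
  array(clip01(pred), c(d[1], d[2], 3))
}

#' @export
print.color_model <- function(x, ...) {
  cat("<color_model> PLS2 with", x$n_components,
      "component(s); training RMSE", sprintf("%.4g", x$rmse), "\n")
  invisible(x)
}
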