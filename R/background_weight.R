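## k-means++ initial centers (D^2 sampling); x is n x p.
kmeans_pp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  centers
}

#' k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations (via [stats::kmeans]) started from k-means++ centres;
#' `restarts` independent starts are run under a fixed seed and the solution
#' with the lowest total within-cluster sum of squares is kept, making the
#' result reproducible.
#'
#' @param x numeric matrix `n x p`.
#' @param k number of clusters; reduced (with a warning) if `x` has fewer
#'   distinct rows.
#' @param seed RNG seed.
#' @param restarts number of independent k-means++ starts (default 10).
#' @return A `stats::kmeans` result object.
#' @export
kmeans_seeded <- function(x, k, seed = 0L, restarts = 10L) {
  x <- as.matrix(x)
  nu <- nrow(unique(x))
  if (nu < k) {
    warning("fewer distinct rows (", nu, ") than k = ", k, ": reducing k")
    k <- nu
  }
  if (k > nrow(x)) stop("k exceeds the number of observations")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeans_pp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' Estimate the smooth background weighting mask of a multimodal image
#'
#' The per-pixel 3-vectors are segmented by k-means with `k = 6`; the
#' darkest class -- the cluster whose centre has the lowest sum of squared
#' components -- is taken as background. The binary mask is then cleaned and
#' softened: median filter, morphological closing of the foreground (fills
#' gaps and extends the foreground), morphological opening of the background
#' mask (removes small foreground specks, smooths the specimen contour), and
#' finally a mean filter that turns the binary mask into weights in
#' `[0, 1]` for smooth background removal. Structuring elements are discs.
#'
#' @param mm a [multimodal_image] (typically preprocessed).
#' @param k number of k-means classes (default 6).
#' @param median_radius,close_radius,open_radius,mean_radius disc radii (in
#'   post-downsampling pixels) of the cleanup cascade; a `mean_radius` of 0
#'   leaves the mask binary.
#' @param seed RNG seed for the clustering.
#' @param restarts k-means++ restarts.
#' @return An object of class `background_weight`: list with `weight`
#'   (matrix in `[0, 1]`, 1 = background), the k-means `centers` and the
#'   index of the `background_cluster`.
#' @export
estimate_background_weight <- function(mm, k = 6L, median_radius = 2L,
                                       close_radius = 5L, open_radius = 5L,
                                       mean_radius = 7L, seed = 0L,
                                       restarts = 10L) {
  stopifnot(inherits(mm, "multimodal_image"))
  if (k < 2) stop("`k` must be >= 2")
  d <- dim(mm$channels)
  km <- kmeans_seeded(mm_pixels(mm), k, seed = seed, restarts = restarts)
  bg_cluster <- which.min(rowSums(km$centers^2))
  mask <- matrix(km$cluster == bg_cluster, d[1], d[2])

  if (median_radius >= 1)
    mask <- median_filter_matrix(mask * 1, median_radius) > 0.5
  if (close_radius >= 1) {
    fg <- EBImage::closing((!mask) * 1, disc_brush(close_radius))
    mask <- as.matrix(EBImage::imageData(fg)) < 0.5
  }
  if (open_radius >= 1) {
    op <- EBImage::opening(mask * 1, disc_brush(open_radius))
    mask <- as.matrix(EBImage::imageData(op)) > 0.5
  }
  weight <- if (mean_radius >= 1) clip01(mean_filter_matrix(mask * 1, mean_radius))
            else mask * 1
  structure(list(weight = weight, centers = km$centers,
                 background_cluster = bg_cluster, k = km$centers |> nrow()),
            class = "background_weight")
}

#' @export
print.background_weight <- function(x, ...) {
  cat("<background_weight> ", nrow(x$weight), "x", ncol(x$weight),
      "; background cluster ", x$background_cluster, " of ", x$k,
      "; mean weight ", sprintf("%.3f", mean(x$weight)), "\n", sep = "")
  invisible(x)
}
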