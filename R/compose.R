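#' Composite the pseudo-HE image
#'
#' Per pixel and channel the output is the convex blend
#' `out = bg * white + (1 - bg) * (nuclei ? nuclei_color : color)`,
#' so background regions fade smoothly to white while nuclei are painted
#' dark violet on top of the PLS colour prediction.
#'
#' @param color RGB array `rows x cols x 3` (PLS colour prediction).
#' @param nuclei logical nuclei mask.
#' @param bg a [estimate_background_weight()] result, or a numeric weight
#'   matrix in `[0, 1]` (1 = background).
#' @param nuclei_color RGB triplet for nuclei; default dark violet
#'   `(0.29, 0.13, 0.37)`.
#' @return RGB array of class `pseudo_he_image`, values in `[0, 1]`.
#' @export
compose_pseudo_he <- function(color, nuclei, bg,
                              nuclei_color = c(0.29, 0.13, 0.37)) {
  if (inherits(bg, "background_weight")) bg <- bg$weight
  d <- dim(color)
  if (length(d) != 3L || d[3] != 3L) stop("`color` must be rows x cols x 3")
  if (!identical(dim(nuclei), d[1:2]) || !identical(dim(bg), d[1:2]))
    stop("layer shape mismatch: color, nuclei and bg must align")
  if (min(bg) < 0 || max(bg) > 1) stop("background weights must lie in [0, 1]")
  out <- array(0, d)
  for (ch in 1:3) {
    fgcol <- color[, , ch]
    fgcol[nuclei] <- nuclei_color[ch]
    out[, , ch] <- bg + (1 - bg) * fgcol
  }
  structure(clip01(out), class = "pseudo_he_image",
            nuclei_color = nuclei_color)
}

#' @export
print.pseudo_he_image <- function(x, ...) {
  d <- dim(x)
  cat("<pseudo_he_image> ", d[1], "x", d[2], " px RGB in [0, 1]\n", sep = "")
  invisible(x)
}

#' Convert a pseudo-HE image to a raster for plotting
#' @param x a `pseudo_he_image`.
#' @param ... ignored.
#' @export
as.raster.pseudo_he_image <- function(x, ...) {
  grDevices::as.raster(unclass(x))
}

#' @export
plot.pseudo_he_image <- function(x, ...) {
  plot(as.raster(x), ...)
}

#' Full pseudo-HE staining of a preprocessed multimodal image
#'
#' Runs the three parallel branches -- PLS colour prediction, LDA nuclei
#' mask, k-means background weight -- and composites them. The nuclei
#' overlay is restricted to tissue (background weight below 0.5), since the
#' discriminant is trained on tissue pixels and the dark background would
#' otherwise alias with the nuclei's negative contrast.
#'
#' @param mm a preprocessed [multimodal_image].
#' @param color_model a trained [fit_color_model()] result.
#' @param nuclei_model a trained [fit_nuclei_model()] result, or `NULL` to
#'   skip the nuclei overlay.
#' @param k,median_radius,close_radius,open_radius,mean_radius background
#'   weighting parameters, see [estimate_background_weight()].
#' @param nuclei_color RGB triplet for nuclei.
#' @param seed RNG seed for the background k-means.
#' @return A list of class `pseudo_he_result`: `image` (`pseudo_he_image`),
#'   `color` (raw PLS prediction), `nuclei_mask`, `background`
#'   (`background_weight`).
#' @export
stain_pseudo_he <- function(mm, color_model, nuclei_model = NULL,
                            k = 6L, median_radius = 2L, close_radius = 5L,
                            open_radius = 5L, mean_radius = 7L,
                            nuclei_color = c(0.29, 0.13, 0.37), seed = 0L) {
  stopifnot(inherits(mm, "multimodal_image"))
  color <- predict_color(color_model, mm)
  bg <- estimate_background_weight(mm, k = k, median_radius = median_radius,
                                   close_radius = close_radius,
                                   open_radius = open_radius,
                                   mean_radius = mean_radius, seed = seed)
  d <- dim(mm$channels)
  nuclei <- if (is.null(nuclei_model)) matrix(FALSE, d[1], d[2])
            else predict_nuclei_mask(nuclei_model, mm) & (bg$weight < 0.5)
  img <- compose_pseudo_he(color, nuclei, bg, nuclei_color = nuclei_color)
  structure(list(image = img, color = color, nuclei_mask = nuclei,
                 background = bg),
            class = "pseudo_he_result")
}

#' Persist / restore pseudo-HE models as JSON
#'
#' Stores the PLS colour coefficients, the LDA means, covariance and
#' discriminant, thresholds and the compositing parameters, together with a
#' hash of the serialised content for provenance.
#'
#' @param color_model a `color_model`.
#' @param nuclei_model a `nuclei_model` or `NULL`.
#' @param path output `.json` path.
#' @param extra named list of additional compositing parameters to store.
#' @return `path` invisibly; `load_pseudo_he_model` returns a list with
#'   elements `color_model` and `nuclei_model`.
#' @export
save_pseudo_he_model <- function(color_model, nuclei_model, path,
                                 extra = list()) {
  stopifnot(inherits(color_model, "color_model"))
  obj <- list(
    color = list(x_mean = color_model$x_mean, y_mean = color_model$y_mean,
                 coef = color_model$coef, n_components = color_model$n_components,
                 rmse = color_model$rmse),
    nuclei = if (!is.null(nuclei_model)) list(
      mu0 = nuclei_model$mu0, mu1 = nuclei_model$mu1, cov = nuclei_model$cov,
      w = nuclei_model$w, b = nuclei_model$b, prior1 = nuclei_model$prior1,
      threshold = nuclei_model$threshold, min_area = nuclei_model$min_area),
    extra = extra
  )
  obj$hash <- object_hash(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_pseudo_he_model
#' @export
load_pseudo_he_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- list(x_mean = unlist(obj$color$x_mean),
             y_mean = unlist(obj$color$y_mean),
             coef = matrix(unlist(obj$color$coef), 3, 3),
             n_components = obj$color$n_components,
             rmse = obj$color$rmse, trained = TRUE)
  class(cm) <- "color_model"
  nm <- NULL
  if (!is.null(obj$nuclei) && length(obj$nuclei)) {
    nm <- list(mu0 = unlist(obj$nuclei$mu0), mu1 = unlist(obj$nuclei$mu1),
               cov = matrix(unlist(obj$nuclei$cov), 3, 3),
               w = unlist(obj$nuclei$w), b = obj$nuclei$b,
               prior1 = obj$nuclei$prior1, threshold = obj$nuclei$threshold,
               min_area = as.integer(obj$nuclei$min_area), trained = TRUE)
    class(nm) <- "nuclei_model"
  }
  list(color_model = cm, nuclei_model = nm, extra = obj$extra, hash = obj$hash)
}
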