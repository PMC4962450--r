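#' Vector normalisation of a spectrum
#'
#' Scales to unit Euclidean norm, removing overall intensity differences
#' (focus, section thickness, laser power) while preserving direction.
#'
#' @param spectrum numeric vector with positive Euclidean norm.
#' @return The spectrum scaled to `||s|| = 1`.
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum^2))
  if (!is.finite(nrm) || nrm <= 0)
    stop("cannot vector-normalize a zero-norm spectrum")
  spectrum / nrm
}

#' Standard spectral pre-treatment of a Raman map
#'
#' Per spectrum: crop to the fingerprint window, subtract the SNIP
#' baseline, vector-normalise. Spectra whose corrected Euclidean norm is
#' (numerically) zero are flagged invalid and zeroed; downstream steps drop
#' them.
#'
#' @param map a [raman_map].
#' @param snip_iterations SNIP window half-width (default 15 channels).
#' @param crop_range `(low, high)` wavenumber window in 1/cm, default
#'   `c(600, 1800)` (fingerprint region).
#' @param lls use the SNIP LLS compression (default TRUE).
#' @return A [raman_map] with processed spectra and two extra fields:
#'   `valid` (logical per pixel) and `preprocessing` (parameter record).
#' @export
preprocess_map <- function(map, snip_iterations = 15L,
                           crop_range = c(600, 1800), lls = TRUE) {
  stopifnot(inherits(map, "raman_map"))
  keep <- map$wavenumbers >= crop_range[1] & map$wavenumbers <= crop_range[2]
  if (!any(keep)) stop("empty crop: no wavenumbers inside crop_range")
  wn <- map$wavenumbers[keep]
  Y <- map$spectra[, keep, drop = FALSE]
  B <- snip_baseline_matrix(Y, snip_iterations, lls = lls)
  corrected <- Y - B
  nrm <- sqrt(rowSums(corrected^2))
  valid <- is.finite(nrm) & nrm > 1e-12
  corrected[valid, ] <- corrected[valid, , drop = FALSE] / nrm[valid]
  corrected[!valid, ] <- 0
  out <- raman_map(corrected, wn, map$grid_shape,
                   individual_id = map$individual_id, scan_id = map$scan_id,
                   pixel_labels = map$pixel_labels)
  out$valid <- valid
  out$preprocessing <- list(snip_iterations = snip_iterations,
                            crop_range = crop_range, lls = lls,
                            n_invalid = sum(!valid))
  out
}

#' Principal component compression of spectra
#'
#' Mean-centred PCA via SVD. Loadings are returned as orthonormal rows with
#' a fixed sign convention (each loading's largest-magnitude element is
#' positive) so results are reproducible across platforms.
#'
#' @param spectra numeric matrix `n x p`.
#' @param n_components number of components to retain,
#'   `<= min(n - 1, p)`.
#' @return An object of class `pca_model`: `mean`, `loadings`
#'   (`n_components x p`), `explained_variance` (fractions over all
#'   components, non-increasing), `n_components`.
#' @export
fit_pca <- function(spectra, n_components) {
  spectra <- as.matrix(spectra)
  maxc <- min(nrow(spectra) - 1L, ncol(spectra))
  if (n_components > maxc)
    stop("n_components (", n_components, ") exceeds min(n - 1, p) = ", maxc)
  pc <- prcomp(spectra, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  L <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  flip <- apply(L, 1, function(v) sign(v[which.max(abs(v))]))
  L <- L * ifelse(flip == 0, 1, flip)
  structure(list(mean = pc$center, loadings = L,
                 explained_variance = ev,
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model a `pca_model`.
#' @return `project_pca` returns the `n x n_components` score matrix.
#' @export
project_pca <- function(model, spectra) {
  stopifnot(inherits(model, "pca_model"))
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(model$mean))
    stop("wavenumber dimension mismatch with the PCA model")
  sweep(spectra, 2, model$mean) %*% t(model$loadings)
}

#' Smallest number of components reaching a variance target
#' @param model a `pca_model` (or explained-variance vector).
#' @param target cumulative explained-variance target (default 0.99).
#' @param cap upper bound on the count (default 20).
#' @return Integer component count.
#' @export
choose_n_components <- function(model, target = 0.99, cap = 20L) {
  ev <- if (inherits(model, "pca_model")) model$explained_variance else model
  min(which(cumsum(ev) >= target - 1e-9)[1], cap, length(ev), na.rm = TRUE)
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", x$n_components, "components;",
      sprintf("%.1f%%", 100 * sum(x$explained_variance[seq_len(x$n_components)])),
      "variance retained\n")
  invisible(x)
}
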