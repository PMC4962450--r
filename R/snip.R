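#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak-clipping: for window
#' half-widths `p` running from `iterations` down to 1 (the
#' decreasing-window variant, which erodes peaks less than the increasing
#' one), every interior point is replaced by
#' `min(v[i], (v[i - p] + v[i + p]) / 2)`.
#' With `lls = TRUE` the clipping runs in the compressed
#' log-log-square-root domain `v = log(log(sqrt(y + 1) + 1) + 1)` (applied
#' after shifting the spectrum to be non-negative), which boosts the
#' statistics sensitivity for high-dynamic-range baselines. Points never
#' touched by the clipping return the input value exactly, so a constant
#' spectrum yields a baseline identical to itself.
#'
#' @param spectrum numeric vector of intensities.
#' @param iterations maximum window half-width `m` (default 15 channels);
#'   requires `length(spectrum) > 2 * iterations`.
#' @param lls apply the LLS compression transform (default TRUE).
#' @param decreasing run windows from `m` down to 1 (default) rather than
#'   1 up to `m`.
#' @return Numeric baseline vector, pointwise `<=` the input on
#'   peak-bearing spectra.
#' @export
snip_baseline <- function(spectrum, iterations = 15L, lls = TRUE,
                          decreasing = TRUE) {
  drop(snip_baseline_matrix(matrix(spectrum, nrow = 1), iterations,
                            lls = lls, decreasing = decreasing))
}

## vectorised SNIP over the rows of an n_spectra x n_channels matrix
snip_baseline_matrix <- function(Y, iterations = 15L, lls = TRUE,
                                 decreasing = TRUE) {
  Y <- as.matrix(Y)
  m <- as.integer(iterations)
  n <- ncol(Y)
  if (m < 1L) stop("`iterations` must be >= 1")
  if (n <= 2L * m)
    stop("spectrum too short: need length > 2 * iterations (",
         n, " <= ", 2L * m, ")")
  if (lls) {
    offset <- apply(Y, 1, min)
    V <- log(log(sqrt(Y - offset + 1) + 1) + 1)
  } else {
    offset <- NULL
    V <- Y
  }
  V0 <- V
  windows <- if (decreasing) m:1L else 1L:m
  for (p in windows) {
    i <- (p + 1L):(n - p)
    V[, i] <- pmin(V[, i], (V[, i - p] + V[, i + p]) / 2)
  }
  if (lls) {
    B <- (exp(exp(V) - 1) - 1)^2 - 1 + offset
    ## undo floating-point round-trip error wherever clipping never acted
    untouched <- V == V0
    B[untouched] <- Y[untouched]
  } else {
    B <- V
  }
  B
}

#' Subtract the SNIP baseline from a spectrum
#' @inheritParams snip_baseline
#' @return The baseline-corrected spectrum.
#' @export
snip_correct <- function(spectrum, iterations = 15L, lls = TRUE,
                         decreasing = TRUE) {
  spectrum - snip_baseline(spectrum, iterations, lls = lls,
                           decreasing = decreasing)
}
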