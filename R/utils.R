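#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards.  All stochastic entry points route through
## this so that identical (params, seed) give bit-identical output.
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
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' Reproducibility with stage independence: one master seed in a pipeline
#' configuration, per-stage seeds derived by a fixed counter scheme so that
#' adding a stage does not perturb the streams of the others.
#'
#' @param seed master seed (integer).
#' @param stage stage counter (non-negative integer).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729 + 1) %%
               .Machine$integer.max)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Reflection-pad a matrix by `r` pixels on every side (edge row/col not
## duplicated, i.e. "symmetric without the boundary" a la reflect_101 when
## possible; falls back to edge duplication for tiny inputs).
pad_reflect <- function(m, r) {
  refl <- function(n) {
    idx <- c((r + 1):2, 1:n, (n - 1):(n - r))
    as.integer(pmin(pmax(idx, 1L), n))
  }
  m[refl(nrow(m)), refl(ncol(m)), drop = FALSE]
}

## Exact per-row median over the columns of `m` (n x K), fully vectorised:
## odd-even transposition sort of the K columns, then pick/average the
## middle order statistics.
row_median_sorted <- function(m) {
  K <- ncol(m)
  for (pass in seq_len(K)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    if (start > K - 1L) next
    j <- seq.int(start, K - 1L, by = 2L)
    a <- m[, j, drop = FALSE]; b <- m[, j + 1L, drop = FALSE]
    lo <- pmin(a, b)
    m[, j] <- lo
    m[, j + 1L] <- a + b - lo
  }
  if (K %% 2 == 1) m[, (K + 1L) %/% 2L]
  else (m[, K %/% 2L] + m[, K %/% 2L + 1L]) / 2
}

## Sliding-window exact median filter on a matrix with reflection edges.
median_filter_matrix <- function(m, radius) {
  stopifnot(radius >= 1)
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, radius)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  stack <- matrix(0, nr * nc, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    stack[, i] <- p[(radius + 1 + offs$dr[i]):(radius + nr + offs$dr[i]),
                    (radius + 1 + offs$dc[i]):(radius + nc + offs$dc[i])]
  }
  matrix(row_median_sorted(stack), nr, nc)
}

## Separable Gaussian blur with replicate edges, via EBImage::filter2 on a
## padded image (filter2 itself is circular; padding removes wrap-around).
gaussian_blur_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- matrix(0, nrow(m) + 2 * r, ncol(m) + 2 * r)
  pr <- pmin(pmax(seq_len(nrow(pad)) - r, 1), nrow(m))
  pc <- pmin(pmax(seq_len(ncol(pad)) - r, 1), ncol(m))
  pad <- m[pr, pc, drop = FALSE]
  ## separable: column-direction then row-direction 1-D convolutions
  cv <- function(x) as.numeric(stats::filter(x, k, sides = 2))
  tmp <- apply(pad, 2, cv)
  tmp2 <- t(apply(tmp, 1, cv))
  tmp2[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

## Disc-shaped morphological structuring element.
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

## Mean filter with a normalised disc kernel, replicate edges.
mean_filter_matrix <- function(m, radius) {
  if (radius < 1) return(m)
  b <- disc_brush(radius); b <- b / sum(b)
  r <- (nrow(b) - 1L) %/% 2L
  pr <- pmin(pmax(seq_len(nrow(m) + 2 * r) - r, 1), nrow(m))
  pc <- pmin(pmax(seq_len(ncol(m) + 2 * r) - r, 1), ncol(m))
  pad <- m[pr, pc, drop = FALSE]
  f <- EBImage::filter2(pad, b)
  as.matrix(f)[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

## Intersection-over-union of two logical masks.
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

## md5 of a serialised R object (config provenance hash).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
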