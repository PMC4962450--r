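#' Weighted k-nearest-neighbour classifier
#'
#' Stores the training spectra features and labels together with the
#' neighbourhood size `k`, the Minkowski distance order `p` and the kernel
#' used to weight neighbour votes. With the default `k = 1` every kernel
#' reduces to plain nearest-neighbour classification.
#'
#' @param features training matrix `n x d`.
#' @param labels training class labels (factor or coercible).
#' @param k number of neighbours (default 1).
#' @param p Minkowski order (`>= 1`, default 2 = Euclidean).
#' @param kernel `"optimal"` (Epanechnikov weighting of rank-normalised
#'   distances, the asymptotically optimal scheme) or `"rectangular"`
#'   (unweighted vote).
#' @return An object of class `kknn_model`.
#' @export
kknn_fit <- function(features, labels, k = 1L, p = 2, kernel = "optimal") {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) == 0L) stop("empty training set")
  if (length(labels) != nrow(features)) stop("label length mismatch")
  if (k < 1L) stop("`k` must be >= 1")
  if (p < 1) stop("Minkowski order `p` must be >= 1")
  kernel <- match.arg(kernel, c("optimal", "rectangular"))
  structure(list(features = features, labels = labels, k = as.integer(k),
                 p = p, kernel = kernel),
            class = "kknn_model")
}

## Minkowski-p distances between query block (m x d) and training (n x d).
## p = 2 uses the BLAS |a|^2 + |b|^2 - 2ab expansion; other p fall back to a
## per-dimension accumulation.
minkowski_dist <- function(Q, X, p) {
  if (p == 2) {
    d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
    sqrt(pmax(d2, 0))
  } else {
    acc <- matrix(0, nrow(Q), nrow(X))
    for (j in seq_len(ncol(Q)))
      acc <- acc + abs(outer(Q[, j], X[, j], "-"))^p
    acc^(1 / p)
  }
}

#' Predict classes with a weighted kNN model
#'
#' For each query the `k` nearest training rows by Minkowski-`p` distance
#' are found; their distances are rank-normalised by the `(k + 1)`-th
#' neighbour distance, kernel weights are applied and the class with the
#' largest summed weight wins. Ties (equal distances or equal vote sums)
#' are broken deterministically: neighbours are ordered by (distance,
#' training-row order) and vote ties go to the smallest class index.
#'
#' @param model a [kknn_fit()] result.
#' @param queries numeric matrix `m x d`.
#' @param chunk_size queries processed per block (memory control).
#' @return A list: `labels` (factor of predictions) and `weights`
#'   (`m x n_classes` matrix of summed vote weights).
#' @export
kknn_predict <- function(model, queries, chunk_size = 512L) {
  stopifnot(inherits(model, "kknn_model"))
  queries <- as.matrix(queries)
  if (ncol(queries) != ncol(model$features))
    stop("feature dimension mismatch: queries have ", ncol(queries),
         ", model has ", ncol(model$features))
  n <- nrow(model$features)
  k <- min(model$k, n)
  lv <- levels(model$labels)
  lab_int <- as.integer(model$labels)
  m <- nrow(queries)
  votes <- matrix(0, m, length(lv), dimnames = list(NULL, lv))
  pred <- integer(m)
  Xn2 <- if (k == 1L && model$p == 2) rowSums(model$features^2) else NULL
  for (start in seq(1L, m, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, m)
    if (k == 1L && model$p == 2) {
      ## nearest neighbour under squared Euclidean distance: argmax of the
      ## linear score 2 q.t - |t|^2, no distance matrix materialised;
      ## "first" implements the earliest-training-row tie-break
      S <- 2 * tcrossprod(queries[idx, , drop = FALSE], model$features)
      S <- S - rep(Xn2, each = length(idx))
      nb <- max.col(S, ties.method = "first")
      ci <- lab_int[nb]
      votes[cbind(idx, ci)] <- 1
      pred[idx] <- ci
      next
    }
    D <- minkowski_dist(queries[idx, , drop = FALSE], model$features, model$p)
    if (k == 1L) {
      nb <- max.col(-D, ties.method = "first")
      ci <- lab_int[nb]
      votes[cbind(idx, ci)] <- 1
      pred[idx] <- ci
      next
    }
    for (ii in seq_along(idx)) {
      d <- D[ii, ]
      ord <- order(d)                      # stable: ties keep row order
      nb <- ord[seq_len(k)]
      w <- if (model$kernel == "rectangular" || k == 1L) {
        rep(1, k)
      } else {
        ## rank-normalise by the (k+1)-th neighbour distance, Epanechnikov
        dk1 <- if (n > k) d[ord[k + 1L]] else d[ord[k]]
        dn <- if (dk1 > 0) d[nb] / dk1 else rep(0, k)
        pmax(0.75 * (1 - pmin(dn, 1)^2), 1e-12)
      }
      vv <- vapply(seq_along(lv),
                   function(ci) sum(w[lab_int[nb] == ci]), numeric(1))
      votes[idx[ii], ] <- vv
      pred[idx[ii]] <- which.max(vv)       # ties -> smallest class index
    }
  }
  list(labels = factor(lv[pred], levels = lv), weights = votes)
}

#' @export
print.kknn_model <- function(x, ...) {
  cat("<kknn_model> ", nrow(x$features), " training spectra, k = ", x$k,
      ", Minkowski p = ", x$p, ", kernel '", x$kernel, "'\n", sep = "")
  invisible(x)
}
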