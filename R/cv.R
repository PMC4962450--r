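#' Confusion-matrix statistics
#'
#' Rows are annotated (true) classes, columns predicted classes. Per class
#' `c` (one-vs-rest): sensitivity = `diag_c / rowsum_c * 100`, specificity
#' = `TN_c / (TN_c + FP_c) * 100`. The mean sensitivity is the unweighted
#' macro-average over classes. A class with zero annotated count has
#' undefined sensitivity, reported as `NA` and omitted from the mean.
#'
#' @param confusion square non-negative numeric matrix with identical row
#'   and column names.
#' @return A list of class `confusion_stats`: `confusion`, `per_class`
#'   (data.frame with `class`, `n`, `sensitivity`, `specificity` in
#'   percent), `mean_sensitivity` (percent).
#' @export
confusion_stats <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  if (is.null(rownames(confusion)))
    rownames(confusion) <- colnames(confusion) <-
      paste0("class", seq_len(nrow(confusion)))
  if (!identical(rownames(confusion), colnames(confusion)))
    stop("row and column class names must match")
  total <- sum(confusion)
  rs <- rowSums(confusion); cs <- colSums(confusion); dg <- diag(confusion)
  sens <- ifelse(rs > 0, dg / rs * 100, NA_real_)
  tn <- total - rs - cs + dg
  fp <- cs - dg
  spec <- ifelse(tn + fp > 0, tn / (tn + fp) * 100, NA_real_)
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = rownames(confusion), n = as.numeric(rs),
                           sensitivity = as.numeric(sens),
                           specificity = as.numeric(spec),
                           row.names = NULL, stringsAsFactors = FALSE),
    mean_sensitivity = mean(sens, na.rm = TRUE)),
    class = "confusion_stats")
}

#' Merge confusion-matrix classes into groups
#'
#' Sums the rows and columns of grouped classes, e.g. adenoma + carcinoma
#' into "tumor" for the tumour-vs-normal diagnosis.
#'
#' @param confusion square named confusion matrix.
#' @param groups named list, e.g.
#'   `list(tumor = c("adenoma", "carcinoma"), normal = "normal")`; classes
#'   not listed keep their own group.
#' @return The merged confusion matrix.
#' @export
merge_confusion <- function(confusion,
                            groups = list(tumor = c("adenoma", "carcinoma"),
                                          normal = "normal")) {
  confusion <- as.matrix(confusion)
  cls <- rownames(confusion)
  grp <- setNames(cls, cls)
  for (g in names(groups)) grp[groups[[g]]] <- g
  gl <- unique(unname(grp))
  out <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in cls) for (j in cls)
    out[grp[[i]], grp[[j]]] <- out[grp[[i]], grp[[j]]] + confusion[i, j]
  out
}

#' Individual-out cross-validation of the SHP classifier
#'
#' One fold per individual: all spectra of that individual are held out,
#' the weighted kNN model is trained on the remaining individuals and the
#' held-out spectra are predicted. Predictions are pooled over folds.
#' At the default region level, each annotated region (scan x class) is
#' scored by the majority vote of its spectrum predictions, matching the
#' granularity of a pathologist's regional diagnosis; spectrum-level
#' scoring is also available.
#'
#' @param dataset an [assemble_shp_dataset()] result.
#' @param k,p,kernel weighted kNN parameters (see [kknn_fit()]).
#' @param level `"region"` (default) or `"spectrum"`.
#' @return An object of class `cv_report`: `confusion`, `stats`
#'   ([confusion_stats()]), `merged` (tumour/normal confusion) and
#'   `merged_stats`, `level`, `folds` (per-individual records),
#'   `predictions` (per-spectrum data.frame).
#' @export
individual_out_cv <- function(dataset, k = 1L, p = 2, kernel = "optimal",
                              level = c("region", "spectrum")) {
  stopifnot(inherits(dataset, "shp_dataset"))
  level <- match.arg(level)
  inds <- unique(dataset$individual)
  if (length(inds) < 2L) stop("need >= 2 individuals for IO-CV")
  lv <- levels(dataset$class)
  pred <- factor(rep(NA_character_, length(dataset$class)), levels = lv)
  folds <- list()
  for (ind in inds) {
    test <- dataset$individual == ind
    train_cls <- droplevels(dataset$class[!test])
    if (nlevels(train_cls) < nlevels(dataset$class)) {
      missing_cls <- setdiff(lv, levels(train_cls))
      folds[[ind]] <- list(individual = ind, n_test = sum(test),
                           missing_in_training = missing_cls)
    } else {
      folds[[ind]] <- list(individual = ind, n_test = sum(test),
                           missing_in_training = character(0))
    }
    model <- kknn_fit(dataset$features[!test, , drop = FALSE],
                      dataset$class[!test], k = k, p = p, kernel = kernel)
    pred[test] <- kknn_predict(model, dataset$features[test, , drop = FALSE])$labels
    folds[[ind]]$accuracy <-
      mean(pred[test] == dataset$class[test])
  }
  predictions <- data.frame(individual = dataset$individual,
                            scan = dataset$scan, region = dataset$region,
                            annotated = dataset$class, predicted = pred,
                            stringsAsFactors = FALSE)
  if (level == "region") {
    regs <- split(predictions, predictions$region)
    ann <- vapply(regs, function(d) as.character(d$annotated[1]), "")
    prd <- vapply(regs, function(d) {
      tb <- table(factor(d$predicted, levels = lv))
      names(tb)[which.max(tb)]
    }, "")
    confusion <- table(factor(ann, levels = lv), factor(prd, levels = lv))
  } else {
    confusion <- table(predictions$annotated, predictions$predicted)
  }
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- NULL
  st <- confusion_stats(confusion)
  merged <- if (all(c("adenoma", "carcinoma") %in% lv))
    merge_confusion(confusion) else confusion
  structure(list(confusion = confusion, stats = st,
                 merged = merged, merged_stats = confusion_stats(merged),
                 level = level, folds = folds, predictions = predictions,
                 params = list(k = k, p = p, kernel = kernel)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> individual-out CV,", x$level, "level\n")
  print(x$confusion)
  pc <- x$stats$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-10s sensitivity %6.1f %%  specificity %6.1f %%\n",
                pc$class[i], pc$sensitivity[i], pc$specificity[i]))
  cat(sprintf("  mean sensitivity %.2f %%; tumour/normal mean sensitivity %.2f %%\n",
              x$stats$mean_sensitivity, x$merged_stats$mean_sensitivity))
  invisible(x)
}

#' Tidy per-class rates of a CV report
#' @param x a `cv_report`.
#' @param ... ignored.
#' @return A data.frame with one row per class.
#' @export
tidy.cv_report <- function(x, ...) x$stats$per_class

#' One-row summary of a CV report
#' @param x a `cv_report`.
#' @param ... ignored.
#' @return A one-row data.frame with the headline rates.
#' @export
glance.cv_report <- function(x, ...) {
  data.frame(level = x$level,
             n_units = sum(x$confusion),
             mean_sensitivity = x$stats$mean_sensitivity,
             tumor_normal_mean_sensitivity = x$merged_stats$mean_sensitivity,
             accuracy = sum(diag(x$confusion)) / sum(x$confusion) * 100)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Two-sample Wilcoxon screening of PC scores
#'
#' For each listed principal component, a two-sided Mann-Whitney/Wilcoxon
#' rank-sum test compares the score distributions of the two groups (e.g.
#' normal vs tumour). Small samples without ties use the exact null
#' distribution; otherwise the normal approximation with tie correction is
#' used (the [stats::wilcox.test] defaults).
#'
#' @param scores numeric score matrix `n x n_components`.
#' @param group_labels two-level grouping of the rows.
#' @param components integer indices of components to test
#'   (default `3:5`).
#' @return A data.frame with `component` and `p_value`.
#' @export
wilcoxon_screen <- function(scores, group_labels, components = 3:5) {
  scores <- as.matrix(scores)
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  if (any(components > ncol(scores)))
    stop("component index exceeds score columns")
  p <- vapply(components, function(j) {
    suppressWarnings(
      wilcox.test(scores[g == levels(g)[1], j],
                  scores[g == levels(g)[2], j],
                  alternative = "two.sided")$p.value)
  }, numeric(1))
  data.frame(component = as.integer(components), p_value = p)
}
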