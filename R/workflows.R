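## block-mean reduce a matrix by an integer factor
block_reduce <- function(m, factor) {
  nr <- (nrow(m) %/% factor) * factor; nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rb <- rowsum(m, rep(seq_len(nr %/% factor), each = factor))
  t(rowsum(t(rb), rep(seq_len(nc %/% factor), each = factor))) / factor^2
}

block_reduce_mask <- function(mask, factor) block_reduce(mask * 1, factor) > 0.5

block_reduce_rgb <- function(rgb, factor) {
  out <- NULL
  for (ch in 1:3) {
    r <- block_reduce(rgb[, , ch], factor)
    if (is.null(out)) out <- array(0, c(dim(r), 3))
    out[, , ch] <- r
  }
  out
}

#' End-to-end pseudo-HE evaluation on a synthetic scene
#'
#' Runs the full stain pipeline on a generated scene -- preprocessing,
#' colour-model training on the scene's own HE reference (foreground
#' non-nuclei pixels), nuclei-model training on the truth labels, staining
#' -- and scores the result against the ground truth at the downsampled
#' grid: per-channel mean absolute colour error over the non-nuclei
#' foreground, background-weight IoU (thresholded at 0.5) and nuclei-mask
#' IoU.
#'
#' @param scene an `image_scene` from [generate_multimodal_pair()].
#' @param median_radius,factor,limits preprocessing parameters, see
#'   [preprocess_multimodal()].
#' @param n_components PLS components for the colour model.
#' @param seed RNG seed for the background clustering.
#' @param calibrate_threshold tune the nuclei decision threshold on the
#'   training pixels by mask IoU (default TRUE).
#' @param ... further arguments to [stain_pseudo_he()].
#' @return A list: `result` (the `pseudo_he_result`), `he_reference`
#'   (downsampled), `metrics` (list with `color_mae` per channel,
#'   `background_iou`, `nuclei_iou`).
#' @details At the downsampled grid, truth masks are thresholded at 50 %
#'   block coverage; the colour model is trained on -- and the colour error
#'   scored over -- pure foreground blocks (no background or nuclei
#'   content), since mixed blocks belong to neither layer.
#' @export
evaluate_pseudo_he_scene <- function(scene, median_radius = 1L, factor = 4L,
                                     limits = contrast_limits(),
                                     n_components = 3L, seed = 0L,
                                     calibrate_threshold = TRUE, ...) {
  stopifnot(inherits(scene, "image_scene"))
  pp <- preprocess_multimodal(scene$multimodal, median_radius = median_radius,
                              factor = factor, limits = limits)
  he_ds <- block_reduce_rgb(scene$he_reference, factor)
  nuc_frac <- block_reduce(scene$nuclei_mask * 1, factor)
  bg_frac <- block_reduce(scene$background_mask * 1, factor)
  nuc_ds <- nuc_frac > 0.5
  bg_ds <- bg_frac > 0.5
  fg_nonnuc <- bg_frac == 0 & nuc_frac == 0

  cm <- fit_color_model(pp, he_ds, n_components = n_components,
                        mask = fg_nonnuc)
  tissue <- !bg_ds
  train_px <- mm_pixels(pp)[as.vector(tissue), , drop = FALSE]
  nm <- fit_nuclei_model(train_px, nuc_ds[tissue])
  if (calibrate_threshold)
    nm <- calibrate_nuclei_threshold(nm, train_px, nuc_ds[tissue])
  res <- stain_pseudo_he(pp, cm, nm, seed = seed, ...)

  mae <- vapply(1:3, function(ch)
    mean(abs(res$image[, , ch][fg_nonnuc] - he_ds[, , ch][fg_nonnuc])),
    numeric(1))
  metrics <- list(
    color_mae = setNames(mae, c("R", "G", "B")),
    background_iou = mask_iou(res$background$weight > 0.5, bg_ds),
    nuclei_iou = mask_iou(res$nuclei_mask, nuc_ds)
  )
  list(result = res, he_reference = he_ds, truth_nuclei = nuc_ds,
       truth_background = bg_ds, preprocessed = pp,
       color_model = cm, nuclei_model = nm, metrics = metrics)
}

#' Spectral histopathology workflow on a Raman cohort
#'
#' The full SHP chain: per-map spectral pre-treatment (SNIP, vector
#' normalisation), pooled PCA compression, per-scan k-means clustering,
#' annotation transfer (for synthetic cohorts the simulated pathologist
#' maps every cluster to the majority truth class of its pixels), dataset
#' assembly and individual-out cross-validation of the weighted kNN
#' classifier.
#'
#' @param cohort a `raman_cohort` (or a list of annotated [raman_map]s with
#'   truth `pixel_labels`).
#' @param snip_iterations,crop_range,lls pre-treatment parameters.
#' @param variance_target,max_components PCA dimensionality rule: smallest
#'   count reaching `variance_target` cumulative explained variance,
#'   capped at `max_components`.
#' @param k_clusters per-scan k-means k (default 9).
#' @param k,p,kernel weighted kNN parameters (defaults: one neighbour,
#'   Minkowski order 2, "optimal" kernel).
#' @param level scoring level for the CV, `"region"` or `"spectrum"`.
#' @param seed master seed; per-scan clustering seeds are derived from it.
#' @return A list of class `shp_result`: `cv` (a `cv_report`), `dataset`,
#'   `pca`, `n_components`, `annotations`.
#' @export
shp_pipeline <- function(cohort, snip_iterations = 15L,
                         crop_range = c(600, 1800), lls = TRUE,
                         variance_target = 0.99, max_components = 20L,
                         k_clusters = 9L, k = 1L, p = 2, kernel = "optimal",
                         level = "region", seed = 0L) {
  maps <- if (inherits(cohort, "raman_cohort")) cohort$maps else cohort
  pp <- lapply(maps, preprocess_map, snip_iterations = snip_iterations,
               crop_range = crop_range, lls = lls)
  pooled <- do.call(rbind, lapply(pp, function(m)
    m$spectra[m$valid, , drop = FALSE]))
  pca <- fit_pca(pooled, n_components = min(max_components,
                                            nrow(pooled) - 1L,
                                            ncol(pooled)))
  ncomp <- choose_n_components(pca, target = variance_target,
                               cap = max_components)
  scores <- lapply(pp, function(m)
    project_pca(pca, m$spectra)[, seq_len(ncomp), drop = FALSE])

  annotations <- vector("list", length(pp))
  for (i in seq_along(pp)) {
    cl <- cluster_scan(scores[[i]], k = min(k_clusters, nrow(scores[[i]])),
                       seed = derive_seed(seed, i))
    truth <- pp[[i]]$pixel_labels
    if (is.null(truth))
      stop("map ", i, " carries no pixel labels for annotation transfer")
    mapping <- majority_truth_mapping(cl, truth)
    annotations[[i]] <- transfer_annotation(cl, mapping)
  }
  dataset <- assemble_shp_dataset(scores, annotations, pp)
  cv <- individual_out_cv(dataset, k = k, p = p, kernel = kernel,
                          level = level)
  structure(list(cv = cv, dataset = dataset, pca = pca,
                 n_components = ncomp, annotations = annotations),
            class = "shp_result")
}

#' @export
print.shp_result <- function(x, ...) {
  cat("<shp_result> ", x$n_components, " PC features\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' Permutation control: shuffle class labels at region granularity
#'
#' Randomly permutes the class assignment across annotated regions while
#' keeping the spectra-to-region structure intact; used as a negative
#' control, where mean sensitivity should fall to chance level.
#'
#' @param dataset an `shp_dataset`.
#' @param seed RNG seed.
#' @return A new `shp_dataset` with permuted classes.
#' @export
shuffle_region_labels <- function(dataset, seed = 0L) {
  stopifnot(inherits(dataset, "shp_dataset"))
  regs <- unique(dataset$region)
  reg_class <- vapply(regs, function(r)
    as.character(dataset$class[dataset$region == r][1]), "")
  with_seed(seed, {
    perm <- sample(reg_class)
    names(perm) <- regs
    out <- dataset
    out$class <- factor(unname(perm[dataset$region]),
                        levels = levels(dataset$class))
    out
  })
}
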