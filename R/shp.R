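#' Excluded annotation classes
#'
#' Morphologic areas and artefacts removed before classifier training:
#' muscle, connective tissue, background, spikes and (occurring only once
#' in typical cohorts) hyperplasia.
#' @return Character vector of class names.
#' @export
shp_excluded_classes <- function() {
  c("muscle", "connective", "background", "spikes", "hyperplasia")
}

shp_diagnostic_classes <- function() c("adenoma", "carcinoma", "normal")

#' k-means clustering of one Raman scan
#'
#' Clusters the per-spectrum feature vectors (typically PC scores) into
#' `k` groups; annotation transfer then maps each cluster to a pathology
#' class. `k` between 9 and 15 matches region granularity for 34 x 40
#' scans.
#'
#' @param features numeric matrix `n_spectra x n_features`.
#' @param k number of clusters (`<= n_spectra`).
#' @param seed RNG seed.
#' @param restarts k-means++ restarts (default 10).
#' @return Integer cluster labels `1..k`.
#' @export
cluster_scan <- function(features, k = 9L, seed = 0L, restarts = 10L) {
  features <- as.matrix(features)
  if (k > nrow(features))
    stop("k (", k, ") exceeds the number of spectra (", nrow(features), ")")
  if (k == 1L) return(rep(1L, nrow(features)))
  km <- kmeans_seeded(features, k, seed = seed, restarts = restarts)
  as.integer(km$cluster)
}

#' Transfer a per-cluster annotation to every spectrum
#'
#' Each spectrum inherits the pathology class of its cluster; clusters
#' mapped to an excluded class are marked for removal.
#'
#' @param cluster_labels integer cluster labels.
#' @param mapping named character vector or list, names = cluster ids
#'   (as character), values = class names; must cover every observed
#'   cluster.
#' @return A data.frame with columns `class` and `excluded`.
#' @export
transfer_annotation <- function(cluster_labels, mapping) {
  mapping <- unlist(mapping)
  observed <- sort(unique(as.integer(cluster_labels)))
  missing <- setdiff(as.character(observed), names(mapping))
  if (length(missing))
    stop("unmapped cluster id(s): ", paste(missing, collapse = ", "))
  cls <- unname(mapping[as.character(cluster_labels)])
  data.frame(class = cls,
             excluded = cls %in% shp_excluded_classes(),
             stringsAsFactors = FALSE)
}

#' Simulated pathologist: map clusters to their majority truth class
#'
#' For synthetic cohorts the blinded annotation step is emulated by
#' assigning each cluster the majority truth class of its member pixels.
#'
#' @param cluster_labels integer cluster labels.
#' @param truth_labels per-pixel truth class labels.
#' @return Named character vector usable as `mapping` in
#'   [transfer_annotation()].
#' @export
majority_truth_mapping <- function(cluster_labels, truth_labels) {
  stopifnot(length(cluster_labels) == length(truth_labels))
  tapply(truth_labels, as.integer(cluster_labels), function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    names(tb)[1]
  })
}

#' Assemble the SHP classification dataset from annotated maps
#'
#' Concatenates the retained (non-excluded, valid) spectra of all maps,
#' attaching per-spectrum class, individual, scan and region identifiers. A
#' region is a contiguous annotated area; here it is identified as
#' scan x class, matching the granularity at which a pathologist diagnoses
#' one measured area.
#'
#' @param features list of per-map feature matrices (same column count).
#' @param annotations list of per-map annotation data.frames from
#'   [transfer_annotation()].
#' @param maps list of [raman_map] objects (source of ids and validity
#'   flags).
#' @return A list of class `shp_dataset`: `features`, `class` (factor over
#'   adenoma/carcinoma/normal), `individual`, `scan`, `region`, and a
#'   `counts` summary. Errors if nothing remains or only one individual is
#'   left; warns when a class occurs in a single individual.
#' @export
assemble_shp_dataset <- function(features, annotations, maps) {
  stopifnot(length(features) == length(annotations),
            length(features) == length(maps))
  Xs <- list(); cls <- list(); ind <- list(); scn <- list()
  total <- 0L; retained <- 0L
  for (i in seq_along(maps)) {
    ann <- annotations[[i]]
    valid <- if (!is.null(maps[[i]]$valid)) maps[[i]]$valid
             else rep(TRUE, nrow(ann))
    keep <- !ann$excluded & valid &
      ann$class %in% shp_diagnostic_classes()
    total <- total + nrow(ann); retained <- retained + sum(keep)
    if (!any(keep)) next
    Xs[[length(Xs) + 1L]] <- as.matrix(features[[i]])[keep, , drop = FALSE]
    cls[[length(cls) + 1L]] <- ann$class[keep]
    ind[[length(ind) + 1L]] <- rep(maps[[i]]$individual_id, sum(keep))
    scn[[length(scn) + 1L]] <- rep(maps[[i]]$scan_id, sum(keep))
  }
  if (!length(Xs)) stop("empty dataset: all spectra excluded")
  X <- do.call(rbind, Xs)
  cls <- factor(unlist(cls), levels = shp_diagnostic_classes())
  cls <- droplevels(cls)
  ind <- unlist(ind); scn <- unlist(scn)
  if (length(unique(ind)) < 2L)
    stop("individual-out cross-validation needs >= 2 individuals")
  per_ind <- table(cls, ind)
  single <- rownames(per_ind)[rowSums(per_ind > 0) == 1L]
  if (length(single))
    warning("class(es) present in only one individual: ",
            paste(single, collapse = ", "),
            " (CV folds will lack them in training)")
  structure(list(features = X, class = cls, individual = ind, scan = scn,
                 region = paste(scn, cls, sep = ":"),
                 counts = list(total = total, retained = retained,
                               excluded = total - retained,
                               per_class = table(cls),
                               per_individual = table(ind))),
            class = "shp_dataset")
}

#' @export
print.shp_dataset <- function(x, ...) {
  cat("<shp_dataset> ", nrow(x$features), " spectra x ",
      ncol(x$features), " features; ",
      length(unique(x$individual)), " individuals, ",
      length(unique(x$region)), " regions\n  classes: ",
      paste(names(x$counts$per_class), x$counts$per_class,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
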