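#' Default pipeline configuration
#'
#' The full configuration schema of [run_pipeline()], with defaults. Any
#' subset may be overridden via a YAML file or a nested list; unknown keys
#' are rejected by [validate_run_config()].
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1L,
    out_dir = "spectropath_out",
    stages = c("synth_images", "pseudo_he", "synth_raman", "shp"),
    images = list(
      image_shape = c(512L, 512L), tile_shape = c(128L, 128L),
      n_nuclei = 150L, nuclei_radius_range = c(8, 14),
      lipid_blob_density = 0.08, fiber_density = 0.03,
      background_fraction = 0.3, vignetting_strength = 0.3,
      noise_sd = 0.02),
    preprocess = list(
      median_radius = 1L, factor = 4L,
      limits = list(cars = c(0.05, 0.015), tpef = c(0.05, 0.04),
                    shg = c(0.001, 0.001))),
    pseudo_he = list(
      n_components = 3L, k = 6L, median_radius = 2L, close_radius = 5L,
      open_radius = 5L, mean_radius = 7L,
      nuclei_color = c(0.29, 0.13, 0.37)),
    raman = list(
      n_individuals = 6L, scans_per_individual = 6L,
      grid_shape = c(34L, 40L), band_width = 8, baseline_order = 3L,
      baseline_amplitude = 3, individual_effect_sd = 0.05, noise_sd = 0.1),
    shp = list(
      snip_iterations = 15L, crop_range = c(600, 1800), lls = TRUE,
      variance_target = 0.99, max_components = 20L, k_clusters = 9L,
      k = 1L, p = 2, kernel = "optimal", level = "region"),
    confusion = list(csv = NULL)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate and complete a pipeline configuration
#'
#' Merges user settings over [default_run_config()]; any key not present in
#' the schema raises an error naming the offending key.
#'
#' @param config a nested list, a YAML file path, or `NULL` for defaults.
#' @return A completed `run_config`.
#' @export
validate_run_config <- function(config = NULL) {
  defaults <- unclass(default_run_config())
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  merge_checked <- function(def, usr, path) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_checked(def[[nm]],
                                   as.list(usr[[nm]]),
                                   paste0(path, nm, "$"))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  cfg <- merge_checked(defaults, as.list(unclass(config)), "")
  bad <- setdiff(cfg$stages,
                 c("synth_images", "pseudo_he", "synth_raman", "shp",
                   "confusion"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a printed confusion matrix from CSV
#'
#' Expects a `class` column followed by one column per predicted class;
#' rows are annotated classes.
#'
#' @param path CSV path.
#' @return A named square integer matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

## stats list for the JSON report
confusion_report <- function(st) {
  list(confusion = st$confusion, per_class = st$per_class,
       mean_sensitivity = st$mean_sensitivity)
}

#' Run the screening pipeline end to end
#'
#' Executes the requested stages in order: synthetic image generation,
#' pseudo-HE staining with truth-based evaluation, synthetic Raman cohort
#' generation, and the SHP classification with individual-out
#' cross-validation. An optional `confusion` stage recomputes the
#' statistics of a printed confusion matrix from CSV. All artifacts land in
#' `out_dir`; `report.json` embeds the full configuration, its hash and
#' every computed statistic, so a rerun with the stored configuration
#' reproduces the deterministic artifacts bit for bit.
#'
#' @param config a `run_config`, nested list, YAML path or `NULL`.
#' @return The report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), config_hash = object_hash(unclass(cfg)),
                 seed = cfg$seed, stages = cfg$stages, results = list())
  scene <- NULL

  if ("synth_images" %in% cfg$stages) {
    sp <- do.call(image_scene_params,
                  c(cfg$images, list(seed = derive_seed(cfg$seed, 1L))))
    scene <- generate_multimodal_pair(sp)
    write_scene(scene, file.path(cfg$out_dir, "scene"))
    report$results$synth_images <- list(
      image_shape = sp$image_shape,
      background_fraction_measured = mean(scene$background_mask),
      nuclei_pixels = sum(scene$nuclei_mask))
  }

  if ("pseudo_he" %in% cfg$stages) {
    if (is.null(scene))
      stop("pseudo_he stage requires synth_images in this configuration")
    lim <- contrast_limits(cfg$preprocess$limits$cars,
                           cfg$preprocess$limits$tpef,
                           cfg$preprocess$limits$shg)
    ev <- evaluate_pseudo_he_scene(
      scene, median_radius = cfg$preprocess$median_radius,
      factor = cfg$preprocess$factor, limits = lim,
      n_components = cfg$pseudo_he$n_components,
      seed = derive_seed(cfg$seed, 2L),
      k = cfg$pseudo_he$k, close_radius = cfg$pseudo_he$close_radius,
      open_radius = cfg$pseudo_he$open_radius,
      mean_radius = cfg$pseudo_he$mean_radius,
      nuclei_color = cfg$pseudo_he$nuclei_color)
    write_rgb_tiff(unclass(ev$result$image),
                   file.path(cfg$out_dir, "pseudo_he.tif"))
    save_pseudo_he_model(ev$color_model, ev$nuclei_model,
                         file.path(cfg$out_dir, "pseudo_he_model.json"),
                         extra = cfg$pseudo_he)
    report$results$pseudo_he <- list(
      color_mae = ev$metrics$color_mae,
      background_iou = ev$metrics$background_iou,
      nuclei_iou = ev$metrics$nuclei_iou,
      pls_components = ev$color_model$n_components,
      pls_rmse = ev$color_model$rmse)
  }

  cohort <- NULL
  if ("synth_raman" %in% cfg$stages) {
    rp <- do.call(raman_cohort_params,
                  c(cfg$raman, list(seed = derive_seed(cfg$seed, 3L))))
    cohort <- generate_raman_cohort(rp)
    report$results$synth_raman <- list(
      n_maps = length(cohort$maps),
      spectra_per_scan = nrow(cohort$maps[[1]]$spectra),
      label_counts = as.list(table(unlist(lapply(cohort$maps,
                                                 `[[`, "pixel_labels")))))
  }

  if ("shp" %in% cfg$stages) {
    if (is.null(cohort))
      stop("shp stage requires synth_raman in this configuration")
    sh <- shp_pipeline(cohort,
                       snip_iterations = cfg$shp$snip_iterations,
                       crop_range = cfg$shp$crop_range, lls = cfg$shp$lls,
                       variance_target = cfg$shp$variance_target,
                       max_components = cfg$shp$max_components,
                       k_clusters = cfg$shp$k_clusters, k = cfg$shp$k,
                       p = cfg$shp$p, kernel = cfg$shp$kernel,
                       level = cfg$shp$level,
                       seed = derive_seed(cfg$seed, 4L))
    report$results$shp <- list(
      n_components = sh$n_components,
      level = sh$cv$level,
      three_class = confusion_report(sh$cv$stats),
      tumor_normal = confusion_report(sh$cv$merged_stats))
  }

  if ("confusion" %in% cfg$stages) {
    if (is.null(cfg$confusion$csv))
      stop("confusion stage needs confusion$csv")
    cm <- read_confusion_csv(cfg$confusion$csv)
    st <- confusion_stats(cm)
    mg <- merge_confusion(cm)
    report$results$confusion <- list(
      three_class = confusion_report(st),
      tumor_normal = confusion_report(confusion_stats(mg)))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
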