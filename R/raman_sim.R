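#' Default class band-amplitude table for synthetic Raman cohorts
#'
#' Rows are tissue classes, columns the four marker bands: 785 1/cm (DNA
#' phosphate backbone, elevated in tumour), 1003 1/cm (phenylalanine ring
#' breathing), 1449 1/cm (CH2 deformation) and 1657 1/cm (amide I).
#' Amplitudes are in arbitrary counts; class contrasts at 785 1/cm step by
#' 0.5 between normal, adenoma and carcinoma.
#'
#' @return A numeric matrix `5 classes x 4 bands`.
#' @export
default_band_amplitudes <- function() {
  m <- rbind(
    normal     = c(0.5, 1.0, 1.2, 1.0),
    adenoma    = c(1.0, 0.9, 1.0, 1.1),
    carcinoma  = c(1.5, 0.8, 0.9, 1.3),
    muscle     = c(0.3, 1.2, 1.5, 1.6),
    background = c(0.05, 0.05, 0.05, 0.05)
  )
  colnames(m) <- c("785", "1003", "1449", "1657")
  m
}

#' Default contiguous region layout for a synthetic scan
#'
#' Mirrors tissue-region annotation granularity: the scan's diagnosis class
#' fills the map, a background blob occupies one corner (about 15 % of the
#' area), and every second scan carries a muscle strip along one edge.
#'
#' @param grid_shape `(rows, cols)` of the scan.
#' @param diagnosis class name filling the bulk of the scan.
#' @param scan_index index of the scan (controls corner/strip placement).
#' @return A character matrix of per-pixel class labels.
#' @export
default_region_layout <- function(grid_shape, diagnosis, scan_index = 1L) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  lab <- matrix(diagnosis, nr, nc)
  ## background corner block (~15 % of area), corner rotates with the scan
  br <- max(2L, round(nr * 0.4)); bc <- max(2L, round(nc * 0.4))
  corner <- scan_index %% 4L
  rs <- if (corner %in% c(0L, 1L)) seq_len(br) else (nr - br + 1L):nr
  cs <- if (corner %in% c(0L, 2L)) seq_len(bc) else (nc - bc + 1L):nc
  lab[rs, cs] <- "background"
  ## muscle strip on alternating scans (~10 % of area)
  if (scan_index %% 2L == 0L) {
    ms <- max(1L, round(nr * 0.1))
    lab[(nr - ms + 1L):nr, ] <- ifelse(lab[(nr - ms + 1L):nr, ] == "background",
                                       "background", "muscle")
  }
  lab
}

#' Parameters for a synthetic Raman hyperspectral cohort
#'
#' Each spectrum is a sum of Gaussian marker bands with class- and
#' individual-dependent amplitudes, a smooth fluorescence baseline
#' (low-order polynomial plus a broad Gaussian hump, scaled per pixel) and
#' additive Gaussian noise. Defaults follow the acquisition geometry of
#' colon cryosection scans: 34 x 40 pixel grid (1360 spectra per scan),
#' fingerprint axis 600-1800 1/cm in 2 1/cm steps, 6 individuals with about
#' six scans each.
#'
#' @param n_individuals number of subjects (default 6).
#' @param scans_per_individual scans (maps) per subject (default 6).
#' @param grid_shape scan grid `(rows, cols)`, default `c(34, 40)`.
#' @param wavenumber_axis strictly increasing axis in 1/cm.
#' @param class_band_amplitudes classes x bands amplitude matrix with band
#'   centres (1/cm) as column names; see [default_band_amplitudes()].
#' @param band_width Gaussian band SD in 1/cm (default 8).
#' @param baseline_order polynomial degree of the baseline (default 3).
#' @param baseline_amplitude typical baseline magnitude in counts
#'   (default 3, i.e. a few times the band amplitudes, as for tissue
#'   autofluorescence).
#' @param individual_effect_sd SD of additive per-individual, per-band
#'   amplitude offsets (default 0.05, mild biological variance).
#' @param noise_sd additive Gaussian noise SD in counts (default 0.1).
#' @param class_region_layout function `(grid_shape, diagnosis, scan_index)`
#'   returning a per-pixel label matrix; default [default_region_layout()].
#' @param store_baselines keep the per-pixel truth baselines (default TRUE).
#' @param seed RNG seed.
#' @return A validated list of class `raman_cohort_params`.
#' @export
raman_cohort_params <- function(n_individuals = 6L,
                                scans_per_individual = 6L,
                                grid_shape = c(34L, 40L),
                                wavenumber_axis = seq(600, 1800, by = 2),
                                class_band_amplitudes = default_band_amplitudes(),
                                band_width = 8,
                                baseline_order = 3L,
                                baseline_amplitude = 3,
                                individual_effect_sd = 0.05,
                                noise_sd = 0.1,
                                class_region_layout = default_region_layout,
                                store_baselines = TRUE,
                                seed = 1L) {
  p <- list(n_individuals = as.integer(n_individuals),
            scans_per_individual = as.integer(scans_per_individual),
            grid_shape = as.integer(grid_shape),
            wavenumber_axis = as.numeric(wavenumber_axis),
            class_band_amplitudes = as.matrix(class_band_amplitudes),
            band_width = band_width, baseline_order = as.integer(baseline_order),
            baseline_amplitude = baseline_amplitude,
            individual_effect_sd = individual_effect_sd,
            noise_sd = noise_sd, class_region_layout = class_region_layout,
            store_baselines = isTRUE(store_baselines),
            seed = as.integer(seed))
  if (p$n_individuals < 1L || p$scans_per_individual < 1L)
    stop("cohort sizes must be positive")
  if (any(p$grid_shape < 1L)) stop("grid_shape must be positive")
  if (any(diff(p$wavenumber_axis) <= 0))
    stop("wavenumber_axis must be strictly increasing")
  if (any(p$class_band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  if (is.null(colnames(p$class_band_amplitudes)) ||
      is.null(rownames(p$class_band_amplitudes)))
    stop("class_band_amplitudes needs class rownames and band-centre colnames")
  if (p$band_width <= 0) stop("band_width must be > 0")
  if (p$noise_sd < 0 || p$individual_effect_sd < 0)
    stop("noise/effect SDs must be >= 0")
  class(p) <- "raman_cohort_params"
  p
}

#' Generate a synthetic Raman hyperspectral cohort with known truth
#'
#' Scans cycle through the diagnoses normal, adenoma, carcinoma so every
#' class occurs in every individual (a requirement for individual-out
#' cross-validation). Per-pixel truth labels and (optionally) truth
#' baselines are retained for oracle comparisons.
#'
#' @param params a [raman_cohort_params()] object.
#' @return A list of class `raman_cohort`: `maps` (list of [raman_map] with
#'   `pixel_labels` set to the truth), `diagnoses` (per-scan bulk class),
#'   `truth_baselines` (list of matrices, or `NULL`), `params`.
#' @export
generate_raman_cohort <- function(params) {
  stopifnot(inherits(params, "raman_cohort_params"))
  amp <- params$class_band_amplitudes
  centers <- as.numeric(colnames(amp))
  wn <- params$wavenumber_axis
  ## bands x wavenumbers Gaussian basis, unit peak height
  G <- exp(-outer(centers, wn, function(c0, w) (w - c0)^2) /
             (2 * params$band_width^2))
  diagnoses_pool <- intersect(c("normal", "adenoma", "carcinoma"),
                              rownames(amp))
  if (length(diagnoses_pool) < 2L)
    stop("need at least two diagnostic classes with amplitude profiles")
  with_seed(params$seed, {
    ## per-individual, per-band additive amplitude offsets
    ind_eff <- matrix(rnorm(params$n_individuals * length(centers),
                            sd = params$individual_effect_sd),
                      params$n_individuals, length(centers))
    maps <- list(); baselines <- list(); diagnoses <- character(0)
    n_px <- prod(params$grid_shape)
    scan_counter <- 0L
    for (ind in seq_len(params$n_individuals)) {
      for (s in seq_len(params$scans_per_individual)) {
        scan_counter <- scan_counter + 1L
        diag_class <- diagnoses_pool[((s - 1L) %% length(diagnoses_pool)) + 1L]
        lab <- params$class_region_layout(params$grid_shape, diag_class,
                                          scan_index = scan_counter)
        lab_vec <- as.vector(t(lab))      # row-major pixel order
        lab_vec <- lab_vec[seq_len(n_px)]
        ## class amplitudes per pixel, individual offset added, floored at 0
        A <- amp[lab_vec, , drop = FALSE]
        A <- pmax(sweep(A, 2, ind_eff[ind, ], "+"), 0)
        signal <- A %*% G
        ## baseline: scan-level gentle polynomial + broad fluorescence hump,
        ## per-pixel gain; curvature scales are kept an order of magnitude
        ## broader than the Raman bands (autofluorescence varies slowly over
        ## the fingerprint window), which is what makes baseline removal
        ## well-posed in the first place
        x <- (wn - min(wn)) / diff(range(wn))
        coefs <- rnorm(params$baseline_order + 1L,
                       sd = 0.5 / (1 + (0:params$baseline_order)))
        poly <- drop(outer(x, 0:params$baseline_order, "^") %*% coefs)
        hump_c <- runif(1, 0.3, 0.7); hump_w <- runif(1, 0.4, 0.8)
        hump <- exp(-(x - hump_c)^2 / (2 * hump_w^2))
        base1 <- poly + runif(1, 0.5, 1.5) * hump
        base1 <- base1 - min(base1)
        base1 <- params$baseline_amplitude * base1 / max(max(base1), 1e-9)
        gain <- runif(n_px, 0.9, 1.1)
        baseline <- tcrossprod(gain, base1)
        spectra <- signal + baseline
        if (params$noise_sd > 0)
          spectra <- spectra + matrix(rnorm(length(spectra),
                                            sd = params$noise_sd),
                                      nrow(spectra), ncol(spectra))
        maps[[scan_counter]] <- raman_map(
          spectra, wn, params$grid_shape,
          individual_id = paste0("ind", ind),
          scan_id = paste0("ind", ind, "_scan", s),
          pixel_labels = lab_vec)
        if (params$store_baselines) baselines[[scan_counter]] <- baseline
        diagnoses[scan_counter] <- diag_class
      }
    }
    structure(list(maps = maps, diagnoses = diagnoses,
                   truth_baselines = if (params$store_baselines) baselines
                                     else NULL,
                   params = params),
              class = "raman_cohort")
  })
}

#' @export
print.raman_cohort <- function(x, ...) {
  n_ind <- length(unique(vapply(x$maps, `[[`, "", "individual_id")))
  cat("<raman_cohort> ", length(x$maps), " maps from ", n_ind,
      " individuals; ", nrow(x$maps[[1]]$spectra), " spectra/map, ",
      length(x$maps[[1]]$wavenumbers), " wavenumbers\n", sep = "")
  tb <- table(unlist(lapply(x$maps, `[[`, "pixel_labels")))
  cat("  truth labels:", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write every map of a cohort to a directory as wide CSV
#' @param cohort a `raman_cohort`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_raman_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$maps)
    write_raman_map(m, file.path(dir, paste0(m$scan_id, ".csv")))
  invisible(dir)
}
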