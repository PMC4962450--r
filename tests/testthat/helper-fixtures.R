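## Small fixtures shared across test files; everything is generated in code
## under fixed seeds.

small_scene_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_shape = c(128L, 128L), tile_shape = c(64L, 64L),
         n_nuclei = 25L, nuclei_radius_range = c(4, 7), noise_sd = 0.01,
         seed = seed),
    list(...))
  do.call(image_scene_params, args)
}

small_cohort_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_individuals = 3L, scans_per_individual = 3L,
         grid_shape = c(12L, 14L), seed = seed),
    list(...))
  do.call(raman_cohort_params, args)
}

## random multimodal image wrapper
random_mm <- function(nr = 16L, nc = 16L, seed = 1L, tile_shape = NULL) {
  set.seed(seed)
  multimodal_image(array(runif(nr * nc * 3), c(nr, nc, 3)),
                   tile_shape = tile_shape)
}

## brute-force sliding median with reflection padding (independent oracle)
brute_median <- function(m, radius) {
  pr <- function(mm, r) {
    refl <- function(n) {
      idx <- c((r + 1):2, 1:n, (n - 1):(n - r))
      pmin(pmax(idx, 1L), n)
    }
    mm[refl(nrow(mm)), refl(ncol(mm)), drop = FALSE]
  }
  p <- pr(m, radius)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- median(p[i:(i + 2 * radius), j:(j + 2 * radius)])
  out
}

## assemble an shp_dataset directly from truth labels (no clustering)
truth_dataset <- function(cohort, n_components = 10L) {
  pp <- lapply(cohort$maps, preprocess_map)
  pooled <- do.call(rbind, lapply(pp, function(m)
    m$spectra[m$valid, , drop = FALSE]))
  pca <- fit_pca(pooled, n_components)
  sc <- lapply(pp, function(m) project_pca(pca, m$spectra))
  ann <- lapply(pp, function(m)
    data.frame(class = m$pixel_labels,
               excluded = m$pixel_labels %in% shp_excluded_classes(),
               stringsAsFactors = FALSE))
  assemble_shp_dataset(sc, ann, pp)
}
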