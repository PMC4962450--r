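#' Parameters for a synthetic multimodal / HE image scene
#'
#' Describes a tissue-like scene used to exercise the pseudo-HE pipeline
#' with known ground truth: a dark background region, diffuse cytoplasm
#' (TPEF), bright lipid blobs (CARS), filamentous collagen fibres (SHG),
#' nuclei rendered as negative contrast (multiplicative darkening in all
#' three channels), per-tile vignetting and additive Gaussian noise. The
#' default tile is 128 px, standing in for the instrument's 450 um x 450 um
#' mosaic tiles after downsampling.
#'
#' @param image_shape image size `(rows, cols)` in pixels; must be divisible
#'   by `tile_shape` in both axes.
#' @param tile_shape tile size `(rows, cols)` in pixels.
#' @param n_nuclei number of nuclei discs.
#' @param nuclei_radius_range `(min, max)` nucleus radius in pixels.
#' @param lipid_blob_density fraction of area covered by lipid blobs.
#' @param fiber_density fraction of area covered by collagen fibres.
#' @param background_fraction target fraction of area that is background.
#' @param vignetting_strength tile vignetting depth, in `[0, 1)`; 0 disables
#'   vignetting entirely (illumination field identically 1).
#' @param noise_sd additive Gaussian noise SD (intensity units, images live
#'   in `[0, 1]`).
#' @param seed RNG seed.
#' @return A validated list of class `image_scene_params`.
#' @export
image_scene_params <- function(image_shape = c(512L, 512L),
                               tile_shape = c(128L, 128L),
                               n_nuclei = 150L,
                               nuclei_radius_range = c(8, 14),
                               lipid_blob_density = 0.08,
                               fiber_density = 0.03,
                               background_fraction = 0.3,
                               vignetting_strength = 0.3,
                               noise_sd = 0.02,
                               seed = 1L) {
  p <- list(image_shape = as.integer(image_shape),
            tile_shape = as.integer(tile_shape),
            n_nuclei = as.integer(n_nuclei),
            nuclei_radius_range = as.numeric(nuclei_radius_range),
            lipid_blob_density = lipid_blob_density,
            fiber_density = fiber_density,
            background_fraction = background_fraction,
            vignetting_strength = vignetting_strength,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (any(p$image_shape %% p$tile_shape != 0L))
    stop("image_shape must be divisible by tile_shape in both axes")
  fr <- c(p$lipid_blob_density, p$fiber_density, p$background_fraction)
  if (any(fr < 0 | fr > 1)) stop("density/fraction parameters must lie in [0, 1]")
  if (p$vignetting_strength < 0 || p$vignetting_strength >= 1)
    stop("vignetting_strength must lie in [0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(p$nuclei_radius_range <= 0) || diff(p$nuclei_radius_range) < 0)
    stop("nuclei_radius_range must be increasing and positive")
  class(p) <- "image_scene_params"
  p
}

## smooth standardised random field (Gaussian-blurred white noise)
smooth_field <- function(nr, nc, sigma) {
  f <- gaussian_blur_matrix(matrix(rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / sd(f)
}

## fixed affine colour map from (CARS, TPEF, SHG) to HE-like RGB; chosen so
## outputs stay inside (0, 1) for inputs in [0, 1] -- the map is then exactly
## affine, which the PLS colour model can represent without error.
he_color_map <- function() {
  list(intercept = c(0.92, 0.85, 0.88),
       coef = matrix(c(-0.05, -0.25, -0.10,    # R row: CARS, TPEF, SHG
                       -0.15, -0.45, -0.20,    # G
                       -0.05, -0.30,  0.05),   # B
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("R", "G", "B"),
                                     c("CARS", "TPEF", "SHG"))))
}

#' Regenerate the HE reference image from stored truth layers
#'
#' The HE reference is a deterministic function of the clean (noise-free,
#' vignetting-free) scene: a fixed affine colour map of the three channels,
#' overwritten with dark violet inside the nuclei mask and white in the
#' background mask.
#'
#' @param scene an `image_scene` as returned by [generate_multimodal_pair()].
#' @return RGB array `rows x cols x 3`.
#' @export
render_he_reference <- function(scene) {
  cm <- he_color_map()
  d <- dim(scene$clean)
  px <- matrix(scene$clean, d[1] * d[2], 3)
  rgb <- sweep(px %*% t(cm$coef), 2, cm$intercept, "+")
  nuc <- as.vector(scene$nuclei_mask)
  bg <- as.vector(scene$background_mask)
  for (ch in 1:3) {
    rgb[nuc, ch] <- scene$nuclei_color[ch]
    rgb[bg, ch] <- 1
  }
  array(clip01(rgb), dim = d)
}

#' Generate a paired multimodal image and HE reference with ground truth
#'
#' Builds a synthetic tissue scene and returns both the "measured"
#' multimodal image (vignetting and noise applied) and the clean truth
#' layers: the noise-free scene, nuclei and background masks, the per-tile
#' illumination field and the HE reference image. Nuclei appear as negative
#' contrast: each nucleus darkens all three channels by a multiplicative
#' factor drawn from `[0.2, 0.5]`.
#'
#' @param params an [image_scene_params()] object.
#' @return A list of class `image_scene` with elements `multimodal`
#'   ([multimodal_image]), `clean` (rows x cols x 3 array),
#'   `he_reference`, `nuclei_mask`, `background_mask`,
#'   `illumination_field`, `nuclei_color` and `params`.
#' @export
generate_multimodal_pair <- function(params) {
  stopifnot(inherits(params, "image_scene_params"))
  with_seed(params$seed, {
    nr <- params$image_shape[1]; nc <- params$image_shape[2]

    ## background: the area beyond the specimen contour -- one large
    ## connected region anchored to a random image side, with a wavy
    ## boundary; thresholding at the quantile makes the area fraction
    ## (up to ties) exactly background_fraction
    theta <- runif(1, 0, 2 * pi)
    ramp <- outer(seq(-1, 1, length.out = nr) * cos(theta),
                  rep(1, nc)) +
            outer(rep(1, nr), seq(-1, 1, length.out = nc) * sin(theta))
    bgf <- 2 * ramp + smooth_field(nr, nc, sigma = min(nr, nc) / 10)
    background_mask <- bgf <= quantile(bgf, params$background_fraction)

    ## TPEF: diffuse cytoplasm with slow spatial variation
    tpef <- clip01(0.55 + 0.12 * smooth_field(nr, nc, min(nr, nc) / 16))

    ## CARS: dim protein signal plus bright lipid blobs
    lipf <- smooth_field(nr, nc, sigma = 6)
    lipid <- lipf >= quantile(lipf, 1 - params$lipid_blob_density)
    cars <- clip01(0.18 + 0.06 * smooth_field(nr, nc, min(nr, nc) / 16) +
                     0.6 * gaussian_blur_matrix(lipid * 1, 1.5))

    ## SHG: sparse filamentous fibres (random line segments, lightly blurred)
    fib <- matrix(0, nr, nc)
    n_fib <- round(params$fiber_density * nr * nc / 120)
    if (n_fib > 0) {
      for (i in seq_len(n_fib)) {
        r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc)
        ang <- runif(1, 0, pi); len <- runif(1, 40, 120)
        t <- seq(0, len, by = 0.5)
        rr <- round(r0 + t * sin(ang)); cc <- round(c0 + t * cos(ang))
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        fib[cbind(rr[ok], cc[ok])] <- 1
      }
      fib <- gaussian_blur_matrix(fib, 0.8)
      fib <- fib / max(max(fib), 1e-12)
    }
    shg <- clip01(0.05 + 0.85 * fib)

    ## nuclei: discs in the foreground, multiplicative darkening 0.2-0.5
    nuclei_mask <- matrix(FALSE, nr, nc)
    darkening <- matrix(1, nr, nc)
    fg_idx <- which(!background_mask)
    if (params$n_nuclei > 0 && length(fg_idx) > 0) {
      centers <- sample(fg_idx, params$n_nuclei, replace = TRUE)
      radii <- runif(params$n_nuclei, params$nuclei_radius_range[1],
                     params$nuclei_radius_range[2])
      factors <- runif(params$n_nuclei, 0.2, 0.5)
      for (i in seq_len(params$n_nuclei)) {
        r0 <- (centers[i] - 1) %% nr + 1
        c0 <- (centers[i] - 1) %/% nr + 1
        rad <- radii[i]; ir <- ceiling(rad)
        rs <- max(1, r0 - ir):min(nr, r0 + ir)
        cs <- max(1, c0 - ir):min(nc, c0 + ir)
        dd <- outer((rs - r0)^2, (cs - c0)^2, "+") <= rad^2
        nuclei_mask[rs, cs] <- nuclei_mask[rs, cs] | dd
        sub <- darkening[rs, cs]
        sub[dd] <- pmin(sub[dd], factors[i])
        darkening[rs, cs] <- sub
      }
    }
    nuclei_mask <- nuclei_mask & !background_mask

    clean <- array(0, c(nr, nc, 3))
    clean[, , 1] <- cars; clean[, , 2] <- tpef; clean[, , 3] <- shg
    for (ch in 1:3) {
      pl <- clean[, , ch] * darkening
      pl[background_mask] <- pl[background_mask] * 0.05
      clean[, , ch] <- pl
    }

    ## per-tile multiplicative vignette: radial falloff times a tile gain
    tr <- params$tile_shape[1]; tc <- params$tile_shape[2]
    ntr <- nr %/% tr; ntc <- nc %/% tc
    illumination_field <- matrix(1, nr, nc)
    if (params$vignetting_strength > 0) {
      rr <- (seq_len(tr) - (tr + 1) / 2) / (tr / 2)
      cc <- (seq_len(tc) - (tc + 1) / 2) / (tc / 2)
      rad2 <- outer(rr^2, cc^2, "+") / 2     # in [0, 1] at tile corners
      vign <- 1 - params$vignetting_strength * rad2
      gains <- matrix(runif(ntr * ntc, 1 - 0.2 * params$vignetting_strength, 1),
                      ntr, ntc)
      for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
        illumination_field[(i - 1) * tr + seq_len(tr),
                           (j - 1) * tc + seq_len(tc)] <- vign * gains[i, j]
      }
    }

    measured <- clean
    for (ch in 1:3) measured[, , ch] <- clean[, , ch] * illumination_field
    if (params$noise_sd > 0)
      measured <- measured + array(rnorm(length(measured), sd = params$noise_sd),
                                   dim = dim(measured))
    measured <- clip01(measured)

    scene <- list(
      multimodal = multimodal_image(measured, tile_shape = params$tile_shape,
                                    provenance = "synthetic scene"),
      clean = clean,
      nuclei_mask = nuclei_mask,
      background_mask = background_mask,
      illumination_field = illumination_field,
      nuclei_color = c(0.29, 0.13, 0.37),
      params = params
    )
    scene$he_reference <- render_he_reference(scene)
    class(scene) <- "image_scene"
    scene
  })
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$clean)
  cat("<image_scene> ", d[1], "x", d[2], " px; ",
      sum(x$background_mask), " background px (",
      sprintf("%.1f%%", 100 * mean(x$background_mask)), "), ",
      sum(x$nuclei_mask), " nuclei px\n", sep = "")
  invisible(x)
}

#' Write all layers of a synthetic scene to a directory
#'
#' Emits per-channel grayscale TIFFs, the fused multimodal RGB, the HE
#' reference, and the truth masks as 8-bit TIFFs.
#'
#' @param scene an `image_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- c("CARS", "TPEF", "SHG")
  for (i in 1:3)
    tiff::writeTIFF(clip01(scene$multimodal$channels[, , i]),
                    file.path(dir, paste0(tolower(ch[i]), ".tif")),
                    bits.per.sample = 32L)
  write_multimodal_tiff(scene$multimodal, file.path(dir, "multimodal.tif"))
  write_rgb_tiff(scene$he_reference, file.path(dir, "he_reference.tif"))
  tiff::writeTIFF(scene$nuclei_mask * 1, file.path(dir, "nuclei_mask.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(scene$background_mask * 1,
                  file.path(dir, "background_mask.tif"), bits.per.sample = 8L)
  invisible(dir)
}
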