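#' Median denoising of a multimodal image
#'
#' Each channel is filtered independently with an exact square sliding
#' median of side `2 * radius + 1`; edges are handled by reflection.
#'
#' @param img a [multimodal_image].
#' @param radius window radius in pixels (`>= 1`).
#' @return A filtered [multimodal_image].
#' @export
median_denoise <- function(img, radius = 1L) {
  stopifnot(inherits(img, "multimodal_image"))
  if (radius < 1) stop("`radius` must be >= 1")
  out <- img$channels
  for (ch in 1:3)
    out[, , ch] <- median_filter_matrix(img$channels[, , ch], as.integer(radius))
  mm_replace(img, out)
}

#' Block-mean downsampling
#'
#' Each output pixel is the arithmetic mean of its `factor x factor` input
#' block. If the image dimensions are not divisible by `factor` the image is
#' cropped to the largest divisible extent (with a message). Tile metadata is
#' rescaled when the tile size is divisible by `factor`, otherwise dropped.
#'
#' @param img a [multimodal_image].
#' @param factor integer downsampling factor (default 4).
#' @return A downsampled [multimodal_image].
#' @export
downsample <- function(img, factor = 4L) {
  stopifnot(inherits(img, "multimodal_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("`factor` must be a positive integer")
  if (factor == 1L) return(img)
  d <- dim(img$channels)
  nr <- (d[1] %/% factor) * factor; nc <- (d[2] %/% factor) * factor
  if (nr != d[1] || nc != d[2])
    message("downsample: cropping ", d[1], "x", d[2], " to ", nr, "x", nc)
  out <- array(0, c(nr %/% factor, nc %/% factor, 3))
  for (ch in 1:3) {
    m <- img$channels[seq_len(nr), seq_len(nc), ch]
    ## sum over row blocks then column blocks
    rb <- rowsum(m, rep(seq_len(nr %/% factor), each = factor))
    cb <- t(rowsum(t(rb), rep(seq_len(nc %/% factor), each = factor)))
    out[, , ch] <- cb / factor^2
  }
  ts <- img$tile_shape
  if (!is.null(ts)) {
    ts <- if (all(ts %% factor == 0L)) ts %/% factor else NULL
  }
  mm_replace(img, out, tile_shape = ts)
}

#' Flat-field illumination correction of mosaic tile scans
#'
#' Mosaic tile scans show a smooth intensity falloff (vignetting) within
#' each tile, plus tile-to-tile gain differences. Two retrospective
#' estimators of the multiplicative illumination field are available, both
#' deterministic and needing no calibration image:
#'
#' * `"mosaic"` (default): one shared field per channel, estimated as the
#'   per-pixel median over all median-normalised tiles and smoothed with a
#'   Gaussian (sigma = tile side / 4). Because every tile is recorded
#'   through the same optics, averaging across tiles cancels specimen
#'   structure while the common vignette remains; the median makes the
#'   estimate robust against tiles dominated by background, which are also
#'   excluded (tile median below half the global level). Tile gains are
#'   equalised via the ratio of the tile's median to the global median
#'   (dim background tiles keep their level), so two tiles with identical
#'   content but different gains correct to the same result.
#' * `"tile"`: the field is a heavy Gaussian blur of each tile itself.
#'   This variant needs no second tile but confounds specimen structure at
#'   the blur scale with the vignette, and flattens the brightness of
#'   background-only tiles.
#'
#' In both variants the field is floored at `eps` of its own median to
#' avoid division blow-up, and each channel is rescaled to preserve its
#' original global mean.
#'
#' @param img a [multimodal_image] with tile metadata.
#' @param method `"mosaic"` or `"tile"`.
#' @param eps flooring fraction applied to the estimated field.
#' @return A corrected [multimodal_image].
#' @export
correct_tile_illumination <- function(img, method = c("mosaic", "tile"),
                                      eps = 0.05) {
  stopifnot(inherits(img, "multimodal_image"))
  method <- match.arg(method)
  if (is.null(img$tile_shape))
    stop("image carries no tile_shape metadata")
  d <- dim(img$channels)
  tr <- img$tile_shape[1]; tc <- img$tile_shape[2]
  if (any(c(d[1] %% tr, d[2] %% tc) != 0L))
    stop("tile grid misaligned: image shape not divisible by tile_shape")
  ntr <- d[1] %/% tr; ntc <- d[2] %/% tc
  sigma <- max(tr, tc) / 4
  out <- img$channels
  for (ch in 1:3) {
    orig_mean <- mean(out[, , ch])
    tiles <- vector("list", ntr * ntc)
    meds <- numeric(ntr * ntc)
    t_idx <- 0L
    for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
      t_idx <- t_idx + 1L
      tiles[[t_idx]] <- out[(i - 1) * tr + seq_len(tr),
                            (j - 1) * tc + seq_len(tc), ch]
      meds[t_idx] <- median(tiles[[t_idx]])
    }
    if (method == "mosaic") {
      glevel <- median(meds)
      keep <- meds >= 0.5 * glevel & meds > 0
      if (sum(keep) < 2L) keep <- meds > 0
      if (!any(keep)) { next }                 # all-zero channel: leave as is
      stack <- vapply(tiles[keep], function(t)
        as.vector(t / median(t)), numeric(tr * tc))
      field <- matrix(row_median_sorted(stack), tr, tc)
      ## light smoothing only: the cross-tile median already suppresses
      ## specimen structure, and a heavy blur would distort the field at
      ## the tile corners
      field <- gaussian_blur_matrix(field, sigma / 2)
      field <- field / mean(field)
      field <- pmax(field, eps)
      glevel <- median(meds[keep])
      t_idx <- 0L
      for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
        t_idx <- t_idx + 1L
        corr <- tiles[[t_idx]] / field
        if (keep[t_idx]) {
          g <- median(corr) / glevel
          if (is.finite(g) && g > 0) corr <- corr / g
        }
        out[(i - 1) * tr + seq_len(tr), (j - 1) * tc + seq_len(tc), ch] <- corr
      }
    } else {
      t_idx <- 0L
      for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
        t_idx <- t_idx + 1L
        tile <- tiles[[t_idx]]
        field <- gaussian_blur_matrix(tile, sigma)
        field <- pmax(field, eps * max(median(field), .Machine$double.xmin))
        out[(i - 1) * tr + seq_len(tr), (j - 1) * tc + seq_len(tc), ch] <-
          tile / field
      }
    }
    m <- mean(out[, , ch])
    if (m > 0) out[, , ch] <- out[, , ch] * (orig_mean / m)
  }
  mm_replace(img, out)
}

#' Per-channel saturation limits for contrast adjustment
#'
#' The limits follow percentile-clipping convention: for each channel,
#' intensities below the `low_tail` quantile and above the `1 - high_tail`
#' quantile are saturated before rescaling to `[0, 1]`. Defaults are the
#' acquisition settings used for colon mosaics: CARS (0.05, 0.015),
#' TPEF (0.05, 0.04), SHG (0.001, 0.001).
#'
#' @param cars,tpef,shg numeric `(low_tail, high_tail)` pairs in `[0, 1)`.
#' @return A list of class `contrast_limits`.
#' @export
contrast_limits <- function(cars = c(0.05, 0.015),
                            tpef = c(0.05, 0.04),
                            shg = c(0.001, 0.001)) {
  lim <- list(CARS = as.numeric(cars), TPEF = as.numeric(tpef),
              SHG = as.numeric(shg))
  for (nm in names(lim)) {
    l <- lim[[nm]]
    if (length(l) != 2L || any(l < 0) || any(l >= 1) || sum(l) >= 1)
      stop("invalid contrast limits for ", nm,
           ": need (low_tail, high_tail) in [0, 1) with sum < 1")
  }
  class(lim) <- "contrast_limits"
  lim
}

#' Percentile contrast adjustment
#'
#' Per channel: clip at the `low_tail` and `1 - high_tail` quantiles, then
#' rescale linearly to `[0, 1]`. A degenerate channel (equal quantiles) is
#' mapped to zero with a warning.
#'
#' @param img a [multimodal_image].
#' @param limits a [contrast_limits()] object.
#' @return A [multimodal_image] with all channels in `[0, 1]`.
#' @export
adjust_contrast <- function(img, limits = contrast_limits()) {
  stopifnot(inherits(img, "multimodal_image"), inherits(limits, "contrast_limits"))
  out <- img$channels
  for (ch in 1:3) {
    l <- limits[[ch]]
    q <- quantile(out[, , ch], c(l[1], 1 - l[2]), names = FALSE)
    if (q[2] <= q[1]) {
      warning("degenerate channel ", c("CARS", "TPEF", "SHG")[ch],
              ": quantiles equal, channel mapped to 0")
      out[, , ch] <- 0
    } else {
      out[, , ch] <- clip01((out[, , ch] - q[1]) / (q[2] - q[1]))
    }
  }
  mm_replace(img, out)
}

#' Full multimodal preprocessing chain
#'
#' Fixed order: median denoising, block-mean downsampling, per-tile
#' illumination correction, percentile contrast adjustment.
#'
#' @param img a [multimodal_image].
#' @param median_radius median window radius (pixels).
#' @param factor downsampling factor.
#' @param limits a [contrast_limits()] object.
#' @param correct_illumination set `FALSE` to skip the flat-field step for
#'   untiled images.
#' @param illumination_method field estimator, see
#'   [correct_tile_illumination()].
#' @return A preprocessed [multimodal_image] with channels in `[0, 1]`.
#' @export
preprocess_multimodal <- function(img, median_radius = 1L, factor = 4L,
                                  limits = contrast_limits(),
                                  correct_illumination = TRUE,
                                  illumination_method = "mosaic") {
  out <- median_denoise(img, median_radius)
  out <- downsample(out, factor)
  if (correct_illumination && !is.null(out$tile_shape))
    out <- correct_tile_illumination(out, method = illumination_method)
  adjust_contrast(out, limits)
}
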