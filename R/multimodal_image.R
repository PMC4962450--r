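#' Multimodal microscopy image container
#'
#' A three-channel label-free nonlinear microscopy image. The channels carry
#' fixed semantic roles and false-colour assignments: CARS (coherent
#' anti-Stokes Raman scattering, lipid contrast) is displayed in red, TPEF
#' (two-photon excited autofluorescence, cytoplasm) in green, and SHG
#' (second harmonic generation, fibrillar collagen) in blue. Intensities are
#' stored as non-negative floating point; images acquired as tile mosaics
#' carry the tile geometry as metadata so that per-tile illumination
#' correction can locate tile boundaries.
#'
#' @param channels numeric array `rows x cols x 3`, finite and `>= 0`;
#'   channel order CARS, TPEF, SHG.
#' @param tile_shape integer length-2 `(rows, cols)` of one tile, or `NULL`
#'   for untiled images.
#' @param pixel_size pixel pitch in micrometres (metadata only).
#' @param provenance free-text origin note.
#' @return An object of class `multimodal_image`.
#' @export
multimodal_image <- function(channels, tile_shape = NULL, pixel_size = NA_real_,
                             provenance = "") {
  if (length(dim(channels)) != 3L || dim(channels)[3] != 3L)
    stop("`channels` must be a rows x cols x 3 array")
  if (!all(is.finite(channels)))
    stop("channel intensities must be finite")
  if (min(channels) < 0)
    stop("channel intensities must be non-negative")
  dimnames(channels) <- NULL
  if (!is.null(tile_shape)) {
    tile_shape <- as.integer(tile_shape)
    if (length(tile_shape) != 2L || any(tile_shape < 1L))
      stop("`tile_shape` must be two positive integers")
  }
  structure(
    list(channels = channels, tile_shape = tile_shape,
         pixel_size = pixel_size, provenance = provenance),
    class = "multimodal_image"
  )
}

#' @export
print.multimodal_image <- function(x, ...) {
  d <- dim(x$channels)
  cat("<multimodal_image> ", d[1], "x", d[2],
      " px, channels CARS/TPEF/SHG\n", sep = "")
  if (!is.null(x$tile_shape))
    cat("  tile grid: ", d[1] %/% x$tile_shape[1], "x",
        d[2] %/% x$tile_shape[2], " tiles of ",
        x$tile_shape[1], "x", x$tile_shape[2], " px\n", sep = "")
  rng <- range(x$channels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.multimodal_image <- function(x) dim(x$channels)

#' Extract a single channel as a matrix
#' @param img a [multimodal_image].
#' @param which `"CARS"`, `"TPEF"` or `"SHG"` (or index 1:3).
#' @return A numeric matrix.
#' @export
mm_channel <- function(img, which) img$channels[, , which]

## rebuild with new pixel data, keeping metadata
mm_replace <- function(img, channels, tile_shape = img$tile_shape) {
  multimodal_image(channels, tile_shape = tile_shape,
                   pixel_size = img$pixel_size, provenance = img$provenance)
}

## flatten to an n_pixels x 3 matrix (column-major pixel order)
mm_pixels <- function(img) {
  d <- dim(img$channels)
  matrix(img$channels, d[1] * d[2], 3,
         dimnames = list(NULL, c("CARS", "TPEF", "SHG")))
}

#' Write / read a multimodal image as multichannel TIFF
#'
#' Stored as 32-bit float, three samples per pixel, so round trips are
#' lossless for the `[0, 1]` data the pipeline works with.
#'
#' @param img a [multimodal_image].
#' @param path output `.tif` path.
#' @return `write_multimodal_tiff` returns `path` invisibly;
#'   `read_multimodal_tiff` returns a [multimodal_image].
#' @export
write_multimodal_tiff <- function(img, path) {
  tiff::writeTIFF(clip01(img$channels), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_multimodal_tiff
#' @param tile_shape tile geometry to attach on read (TIFF carries none).
#' @export
read_multimodal_tiff <- function(path, tile_shape = NULL) {
  a <- tiff::readTIFF(path)
  multimodal_image(a, tile_shape = tile_shape,
                   provenance = paste("read from", path))
}

#' Write an RGB image (pseudo-HE or reference) as 8-bit TIFF
#' @param rgb numeric array `rows x cols x 3` in `[0, 1]`.
#' @param path output path.
#' @export
write_rgb_tiff <- function(rgb, path) {
  tiff::writeTIFF(clip01(rgb), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_rgb_tiff
#' @export
read_rgb_tiff <- function(path) tiff::readTIFF(path)
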