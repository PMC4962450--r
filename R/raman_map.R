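#' Raman hyperspectral map container
#'
#' One raster scan of Raman spectra: a `pixels x wavenumbers` matrix plus
#' the spatial grid shape and identifiers. Pixels are stored row-major over
#' the grid (`pixel = (row - 1) * cols + col`). Typical acquisition: 5 um
#' step, around 34 x 40 pixels, i.e. about 1360 spectra per scan.
#'
#' @param spectra numeric matrix `n_pixels x n_wavenumbers`, finite.
#' @param wavenumbers strictly increasing numeric axis in 1/cm.
#' @param grid_shape integer `(rows, cols)`; `rows * cols` must equal
#'   `nrow(spectra)`.
#' @param individual_id subject identifier (one per map).
#' @param scan_id scan identifier.
#' @param pixel_labels optional per-pixel class labels (character).
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(spectra, wavenumbers, grid_shape,
                      individual_id = "ind1", scan_id = "scan1",
                      pixel_labels = NULL) {
  spectra <- as.matrix(spectra)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("`grid_shape` must be two positive integers")
  if (nrow(spectra) != prod(grid_shape))
    stop("nrow(spectra) must equal rows * cols of grid_shape")
  if (ncol(spectra) != length(wavenumbers))
    stop("ncol(spectra) must match length(wavenumbers)")
  if (any(diff(wavenumbers) <= 0))
    stop("`wavenumbers` must be strictly increasing")
  if (!all(is.finite(spectra))) stop("spectra must be finite")
  if (!is.null(pixel_labels) && length(pixel_labels) != nrow(spectra))
    stop("pixel_labels length mismatch")
  structure(
    list(spectra = spectra, wavenumbers = as.numeric(wavenumbers),
         grid_shape = grid_shape,
         individual_id = as.character(individual_id),
         scan_id = as.character(scan_id),
         pixel_labels = if (is.null(pixel_labels)) NULL
                        else as.character(pixel_labels)),
    class = "raman_map"
  )
}

#' @export
print.raman_map <- function(x, ...) {
  cat("<raman_map> ", x$grid_shape[1], "x", x$grid_shape[2], " px (",
      nrow(x$spectra), " spectra), ", length(x$wavenumbers),
      " wavenumbers [", min(x$wavenumbers), ", ", max(x$wavenumbers),
      "] 1/cm\n  individual ", x$individual_id, ", scan ", x$scan_id, "\n",
      sep = "")
  if (!is.null(x$pixel_labels)) {
    tb <- table(x$pixel_labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a Raman map as wide CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per pixel: `row`, `col`, optional `label`, then one
#' column per wavenumber (named `wn_<value>`). Grid shape, identifiers and
#' the wavenumber axis are stored in `<path>.meta.json`.
#'
#' @param map a [raman_map].
#' @param path output `.csv` path.
#' @return `path` invisibly; `read_raman_map` returns a [raman_map].
#' @export
write_raman_map <- function(map, path) {
  stopifnot(inherits(map, "raman_map"))
  gs <- map$grid_shape
  df <- data.table::data.table(
    row = rep(seq_len(gs[1]), each = gs[2]),
    col = rep(seq_len(gs[2]), times = gs[1])
  )
  if (!is.null(map$pixel_labels)) df$label <- map$pixel_labels
  sp <- data.table::as.data.table(map$spectra)
  data.table::setnames(sp, paste0("wn_", map$wavenumbers))
  data.table::fwrite(cbind(df, sp), path)
  meta <- list(grid_shape = map$grid_shape, wavenumbers = map$wavenumbers,
               individual_id = map$individual_id, scan_id = map$scan_id,
               has_labels = !is.null(map$pixel_labels))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raman_map
#' @export
read_raman_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  dt <- data.table::fread(path)
  wn_cols <- grep("^wn_", names(dt), value = TRUE)
  spectra <- as.matrix(dt[, wn_cols, with = FALSE])
  dimnames(spectra) <- NULL
  raman_map(spectra, wavenumbers = unlist(meta$wavenumbers),
            grid_shape = unlist(meta$grid_shape),
            individual_id = meta$individual_id, scan_id = meta$scan_id,
            pixel_labels = if (isTRUE(meta$has_labels)) dt$label else NULL)
}
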