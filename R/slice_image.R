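#' Attenuation image on a square (or cubic) grid
#'
#' A `slice_image` is a numeric matrix of linear attenuation coefficients
#' (1/mm) with a voxel size attribute; a `volume_image` is a 3D array with the
#' same convention. Row index runs down the image (+y up in physical
#' coordinates), column index runs right (+x); the physical origin is the grid
#' centre.
#'
#' @param values Numeric matrix (or 3D array for volumes), nonnegative for
#'   physical images.
#' @param voxel_mm Voxel edge length in mm.
#' @return A `slice_image` (or `volume_image`) object.
#' @export
slice_image <- function(values, voxel_mm) {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("'values' must be a matrix", call. = FALSE)
  if (!is.numeric(voxel_mm) || voxel_mm <= 0)
    stop("'voxel_mm' must be positive", call. = FALSE)
  structure(values, voxel_mm = as.numeric(voxel_mm),
            class = c("slice_image", class(values)))
}

#' @rdname slice_image
#' @export
volume_image <- function(values, voxel_mm) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  structure(values, voxel_mm = as.numeric(voxel_mm),
            class = c("volume_image", class(values)))
}

print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d, voxel %g mm, range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "voxel_mm"), min(x), max(x)))
  invisible(x)
}

#' @rdname slice_image
#' @param x Object to query.
#' @export
voxel_size_mm <- function(x) {
  v <- attr(x, "voxel_mm")
  if (is.null(v)) stop("object has no voxel size metadata", call. = FALSE)
  v
}

# strip class/attrs to a plain matrix
as_matrix <- function(x) {
  matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
}

#' Write / read a slice image as 32-bit float TIFF
#'
#' Pixel values are affinely rescaled into `[0, 1]` for storage (TIFF float
#' semantics outside that range are undefined in the writer); the rescale
#' slope/offset and the voxel size travel in a JSON sidecar
#' (`<path>.meta.json`), so the round trip restores physical attenuation
#' values to float-32 precision.
#'
#' @param img A [slice_image()].
#' @param path Output file path.
#' @return `read_slice_tiff` returns a [slice_image()]; `write_slice_tiff`
#'   returns `path` invisibly.
#' @export
write_slice_tiff <- function(img, path) {
  stopifnot(inherits(img, "slice_image"))
  m <- as_matrix(img)
  lo <- min(m); hi <- max(m)
  slope <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / slope, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(list(voxel_mm = voxel_size_mm(img),
                            offset = lo, slope = slope),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slice_tiff
#' @param voxel_mm Voxel size override when the sidecar metadata is missing.
#' @export
read_slice_tiff <- function(path, voxel_mm = NULL) {
  raw <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".meta.json")
  offset <- 0; slope <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    offset <- meta$offset; slope <- meta$slope
    if (is.null(voxel_mm)) voxel_mm <- meta$voxel_mm
  }
  if (is.null(voxel_mm))
    stop("no sidecar metadata found; pass 'voxel_mm'", call. = FALSE)
  slice_image(matrix(as.numeric(raw) * slope + offset, nrow = nrow(raw)),
              voxel_mm)
}

# physical pixel-centre coordinates (mm), origin at grid centre.
# Returns list(x = column coords, y = row coords); y decreases with row index.
grid_coords <- function(n, voxel_mm) {
  idx <- seq_len(n)
  list(x = (idx - (n + 1) / 2) * voxel_mm,
       y = ((n + 1) / 2 - idx) * voxel_mm)
}
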