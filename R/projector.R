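.sm_cache <- new.env(parent = emptyenv())

#' Sparse system matrix for a scan geometry
#'
#' Builds the `M x N` ray-driven system matrix `A` whose entry `a_ij` is the
#' exact intersection length (mm) of projection ray `j` with pixel `i`
#' (Siddon-style parametric traversal). Rays are indexed angle-major
#' (`j = (angle - 1) * det_count + bin`); pixels column-major like
#' `as.vector()` of the image matrix. Forward projection is then the
#' linear-system model `p = A f`.
#'
#' Matrices are cached in-process per (geometry, grid, angle set), since
#' system-matrix construction dominates the cost of iterative studies.
#'
#' @param geom A [scan_geometry()].
#' @param grid_n Image grid side length (pixels).
#' @param voxel_mm Pixel size (mm); defaults to the demagnified detector pitch
#'   [isocenter_voxel_size()].
#' @param angles_deg Projection angles in degrees (e.g.
#'   [projection_angles()]).
#' @param cache Reuse/populate the in-process cache.
#' @return An object of class `system_matrix` wrapping a
#'   `Matrix::dgCMatrix`.
#' @export
build_system_matrix <- function(geom, grid_n, angles_deg,
                                voxel_mm = isocenter_voxel_size(geom) / 1000,
                                cache = TRUE) {
  stopifnot(inherits(geom, "scan_geometry"))
  grid_n <- as.integer(grid_n)
  key <- paste(geom$beam, geom$sod_mm, geom$sid_mm, geom$det_pitch_um,
               geom$det_count, grid_n, signif(voxel_mm, 12),
               paste(signif(angles_deg, 10), collapse = ","), sep = "|")
  key <- paste0("sm", format(sum(utf8ToInt(digest_key <- key)) %% 1e9), "_",
                nchar(key), "_", grid_n, "_", length(angles_deg))
  if (cache && !is.null(.sm_cache[[key]]) &&
      identical(attr(.sm_cache[[key]], "full_key"), digest_key))
    return(.sm_cache[[key]])

  half_fov <- geom$det_count * geom$det_pitch_um / 1000 / 2 *
    geom$sod_mm / geom$sid_mm
  half_diag <- grid_n * voxel_mm * sqrt(2) / 2
  truncated <- half_diag > half_fov + 1e-9
  if (truncated)
    warning("object grid extends beyond the scan field of view; ",
            "peripheral rays are truncated", call. = FALSE)

  tr <- cpp_siddon_trace(grid_n, voxel_mm, geom$det_count,
                         angles_deg * pi / 180,
                         geom$beam == "fan_flat",
                         geom$sod_mm, geom$sid_mm, geom$det_pitch_um / 1000)
  M <- length(angles_deg) * geom$det_count
  N <- grid_n^2
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(M, N))
  sm <- structure(list(A = A, geom = geom, grid_n = grid_n, voxel_mm = voxel_mm,
                       angles_deg = angles_deg, truncated = truncated),
                  class = "system_matrix")
  attr(sm, "full_key") <- digest_key
  if (cache) .sm_cache[[key]] <- sm
  sm
}

print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d rays x %d pixels (%s), %d angles, grid %d @ %.4g mm, %d nonzeros\n",
              nrow(x$A), ncol(x$A), x$geom$beam, length(x$angles_deg),
              x$grid_n, x$voxel_mm, length(x$A@x)))
  invisible(x)
}

# uniform angular step of a system matrix's angle grid (error if non-uniform)
sm_angle_step <- function(sm) {
  if (length(sm$angles_deg) < 2) return(NA_real_)
  d <- diff(sm$angles_deg)
  if (max(abs(d - d[1])) > 1e-9) return(NA_real_)
  d[1]
}

#' Forward projection p = A f
#'
#' @param f A [slice_image()] or matrix matching the system-matrix grid.
#' @param sm A [build_system_matrix()] result.
#' @return A [sinogram()] (`n_angles x det_count`).
#' @export
forward_project <- function(f, sm) {
  stopifnot(inherits(sm, "system_matrix"))
  if (nrow(f) != sm$grid_n || ncol(f) != sm$grid_n)
    stop("shape mismatch between image and system matrix", call. = FALSE)
  p <- as.numeric(sm$A %*% as.vector(as_matrix_any(f)))
  vals <- t(matrix(p, nrow = sm$geom$det_count))
  step <- sm_angle_step(sm)
  sinogram(vals, angle_step_deg = if (is.na(step)) 1 else step,
           angle_start = sm$angles_deg[1],
           bin_pitch_um = sm$geom$det_pitch_um)
}

#' Backprojection (adjoint) A^T p
#'
#' The matched adjoint of [forward_project()]: adjointness
#' `<A f, g> == <f, A^T g>` holds exactly by construction.
#'
#' @param p A [sinogram()] or `n_angles x det_count` matrix.
#' @param sm A [build_system_matrix()] result.
#' @return A [slice_image()].
#' @export
back_project <- function(p, sm) {
  stopifnot(inherits(sm, "system_matrix"))
  vals <- if (inherits(p, "sinogram")) p$values else p
  if (nrow(vals) != length(sm$angles_deg) || ncol(vals) != sm$geom$det_count)
    stop("shape mismatch between sinogram and system matrix", call. = FALSE)
  v <- as.numeric(Matrix::crossprod(sm$A, as.vector(t(vals))))
  slice_image(matrix(v, sm$grid_n, sm$grid_n), sm$voxel_mm)
}

#' Clear the in-process system-matrix cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_system_matrix_cache <- function() {
  n <- length(ls(.sm_cache))
  rm(list = ls(.sm_cache), envir = .sm_cache)
  invisible(n)
}
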