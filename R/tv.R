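#' Total-variation norm of an image or volume
#'
#' Isotropic discrete TV: the sum over voxels of
#' `sqrt(sum of squared forward differences along each axis)`. 2D inputs drop
#' the z term. Forward differences use a zero-gradient boundary (the
#' difference past the last voxel along an axis is 0), so a constant image has
#' TV 0 and TV is positively homogeneous: `tv_norm(c * f) = c * tv_norm(f)`.
#'
#' @param f Matrix, 3D array, [slice_image()] or [volume_image()].
#' @return Nonnegative scalar.
#' @export
tv_norm <- function(f) {
  d <- dim(f)
  if (length(d) == 2) {
    m <- as_matrix_any(f)
    dx <- cbind(m[, -1] - m[, -d[2]], 0)
    dy <- rbind(m[-1, ] - m[-d[1], ], 0)
    sum(sqrt(dx^2 + dy^2))
  } else if (length(d) == 3) {
    a <- array(as.numeric(f), d)
    dx <- a; dx[] <- 0; dx[, -d[2], ] <- a[, -1, ] - a[, -d[2], ]
    dy <- a; dy[] <- 0; dy[-d[1], , ] <- a[-1, , ] - a[-d[1], , ]
    dz <- a; dz[] <- 0; dz[, , -d[3]] <- a[, , -1] - a[, , -d[3]]
    sum(sqrt(dx^2 + dy^2 + dz^2))
  } else stop("'f' must be 2D or 3D", call. = FALSE)
}

#' Smoothed TV norm and its gradient
#'
#' `tv_norm_smoothed` replaces the voxel magnitude by
#' `sqrt(|grad f|^2 + eps^2)`, making the norm differentiable everywhere;
#' `tv_gradient` is its exact analytic gradient (forward differences with
#' zero-gradient boundary, adjoint accumulation). The gradient of a constant
#' image is identically zero.
#'
#' @param f Matrix or 3D array.
#' @param eps Smoothing constant (> 0).
#' @return `tv_norm_smoothed`: scalar. `tv_gradient`: array shaped like `f`.
#' @export
tv_norm_smoothed <- function(f, eps = 1e-6) {
  stopifnot(eps > 0)
  d <- dim(f)
  if (length(d) == 2) {
    m <- as_matrix_any(f)
    dx <- cbind(m[, -1] - m[, -d[2]], 0)
    dy <- rbind(m[-1, ] - m[-d[1], ], 0)
    sum(sqrt(dx^2 + dy^2 + eps^2))
  } else {
    a <- array(as.numeric(f), d)
    dx <- a; dx[] <- 0; dx[, -d[2], ] <- a[, -1, ] - a[, -d[2], ]
    dy <- a; dy[] <- 0; dy[-d[1], , ] <- a[-1, , ] - a[-d[1], , ]
    dz <- a; dz[] <- 0; dz[, , -d[3]] <- a[, , -1] - a[, , -d[3]]
    sum(sqrt(dx^2 + dy^2 + dz^2 + eps^2))
  }
}

#' @rdname tv_norm_smoothed
#' @export
tv_gradient <- function(f, eps = 1e-6) {
  stopifnot(eps > 0)
  d <- dim(f)
  if (length(d) == 2) {
    m <- as_matrix_any(f)
    dx <- cbind(m[, -1] - m[, -d[2]], 0)
    dy <- rbind(m[-1, ] - m[-d[1], ], 0)
    w <- 1 / sqrt(dx^2 + dy^2 + eps^2)
    gx <- dx * w; gy <- dy * w
    # divergence-style adjoint of the forward-difference operator
    g <- -gx - gy
    g[, -1] <- g[, -1] + gx[, -d[2]]
    g[-1, ] <- g[-1, ] + gy[-d[1], ]
    g
  } else {
    a <- array(as.numeric(f), d)
    dx <- a; dx[] <- 0; dx[, -d[2], ] <- a[, -1, ] - a[, -d[2], ]
    dy <- a; dy[] <- 0; dy[-d[1], , ] <- a[-1, , ] - a[-d[1], , ]
    dz <- a; dz[] <- 0; dz[, , -d[3]] <- a[, , -1] - a[, , -d[3]]
    w <- 1 / sqrt(dx^2 + dy^2 + dz^2 + eps^2)
    gx <- dx * w; gy <- dy * w; gz <- dz * w
    g <- -gx - gy - gz
    g[, -1, ] <- g[, -1, ] + gx[, -d[2], ]
    g[-1, , ] <- g[-1, , ] + gy[-d[1], , ]
    g[, , -1] <- g[, , -1] + gz[, , -d[3]]
    g
  }
}
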