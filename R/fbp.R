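#' Reconstruction filter specification
#'
#' @param kernel `"ramlak"` (default; the paper-family band-limited ramp),
#'   `"shepp_logan_filter"` (sinc-apodised ramp) or `"hann"`.
#' @param cutoff Band limit as a fraction of the Nyquist frequency, in (0, 1].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kernel = c("ramlak", "shepp_logan_filter", "hann"),
                        cutoff = 1) {
  kernel <- match.arg(kernel)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("'cutoff' must be in (0, 1]", call. = FALSE)
  structure(list(kernel = kernel, cutoff = cutoff), class = "filter_spec")
}

# frequency response (FFT) of the discrete band-limited ramp kernel of
# Zeng/Kak-Slaney form: h[0] = 1/(4 h^2), h[n odd] = -1/(pi n h)^2.
# The DC bin is forced to zero so constant rows filter to (numerical) zero.
ramp_kernel_fft <- function(L, h_mm, spec) {
  k <- numeric(L)
  k[1] <- 1 / (4 * h_mm^2)
  nmax <- L %/% 2
  odd <- seq(1, nmax, by = 2)
  k[1 + odd] <- -1 / (pi * odd * h_mm)^2
  k[L + 1 - odd] <- -1 / (pi * odd * h_mm)^2
  H <- Re(stats::fft(k))
  H[1] <- 0
  i <- 0:(L - 1)
  frac <- pmin(i, L - i) / (L / 2)   # |f| / f_Nyquist
  w <- as.numeric(frac <= spec$cutoff + 1e-12)
  if (spec$kernel == "hann") {
    w <- w * 0.5 * (1 + cos(pi * frac / spec$cutoff))
  } else if (spec$kernel == "shepp_logan_filter") {
    x <- pi * frac / (2 * spec$cutoff)
    sinc <- ifelse(frac == 0, 1, sin(x) / x)
    w <- w * sinc
  }
  H * w
}

#' Ramp-filter every angular row of a sinogram
#'
#' Frequency-domain convolution with the band-limited discrete ramp kernel
#' (zero-padded to at least twice the row length, so the circular convolution
#' is linear). Filtering is linear; a constant row maps to (numerical) zero
#' and an impulse row returns the discrete kernel itself, with
#' `1/(4 h^2)` at zero lag.
#'
#' @param s A [sinogram()].
#' @param spec A [filter_spec()].
#' @param h_mm Radial sample spacing used in the kernel; defaults to the
#'   sinogram's bin pitch.
#' @param circular When `TRUE`, filter circularly at the row length: the
#'   zeroed DC bin then maps constant rows to exact (numerical) zero, at the
#'   price of wrap-around between the row ends. The padded default is the
#'   correct linear convolution for reconstruction; its response to a
#'   constant row is confined to the row edges (the ramp's DC gain is still
#'   exactly zero).
#' @return A [sinogram()] of filtered rows (same shape and metadata).
#' @export
ramp_filter_rows <- function(s, spec = filter_spec(), h_mm = s$bin_pitch_um / 1000,
                             circular = FALSE) {
  stopifnot(inherits(s, "sinogram"), inherits(spec, "filter_spec"))
  if (!is.finite(h_mm) || h_mm <= 0)
    stop("radial sampling unknown; pass 'h_mm'", call. = FALSE)
  n <- ncol(s$values)
  L <- if (circular) n else 2^ceiling(log2(2 * n))
  H <- ramp_kernel_fft(L, h_mm, spec)
  pad <- matrix(0, nrow(s$values), L)
  pad[, seq_len(n)] <- s$values
  filt <- t(apply(pad, 1, function(row) Re(stats::fft(stats::fft(row) * H,
                                                      inverse = TRUE)) / L))
  sinogram(filt[, seq_len(n), drop = FALSE], s$angle_step_deg, s$angle_start,
           s$bin_pitch_um, known = s$known, completed = s$completed)
}

#' Filtered backprojection reconstruction
#'
#' The 2D central-slice specialisation of the Feldkamp algorithm: fan-flat
#' rows are cosine pre-weighted `sod/sqrt(sod^2 + s^2)` in the demagnified
#' detector coordinate `s`, ramp filtered, and backprojected with the
#' `1/U^2` magnification weight; parallel rows skip the weights. The angular
#' integral is scaled by the step (halved beyond 180 degrees of coverage,
#' where every line is measured twice). Negative values are retained;
#' clipping is the caller's choice.
#'
#' @param s A [sinogram()] (>= 1 angle) whose rows match `geom$det_count`.
#' @param geom The [scan_geometry()] that produced it.
#' @param grid_n Output grid side (pixels).
#' @param voxel_mm Output pixel size; defaults to the demagnified pitch.
#' @param spec A [filter_spec()].
#' @return A [slice_image()].
#' @export
fbp_reconstruct <- function(s, geom, grid_n,
                            voxel_mm = isocenter_voxel_size(geom) / 1000,
                            spec = filter_spec()) {
  stopifnot(inherits(s, "sinogram"), inherits(geom, "scan_geometry"))
  if (ncol(s$values) != geom$det_count)
    stop("geometry mismatch: sinogram bins != det_count", call. = FALSE)
  n_ang <- nrow(s$values)
  grid_n <- as.integer(grid_n)
  pitch_iso <- isocenter_voxel_size(geom) / 1000
  sod <- geom$sod_mm
  det_s <- (seq_len(geom$det_count) - (geom$det_count + 1) / 2) * pitch_iso

  vals <- s$values
  if (geom$beam == "fan_flat") {
    w <- sod / sqrt(sod^2 + det_s^2)
    vals <- sweep(vals, 2, w, `*`)
  }
  filt <- ramp_filter_rows(sinogram(vals, s$angle_step_deg, s$angle_start,
                                    s$bin_pitch_um),
                           spec, h_mm = pitch_iso)$values * pitch_iso

  g <- grid_coords(grid_n, voxel_mm)
  X <- matrix(g$x, grid_n, grid_n, byrow = TRUE)
  Y <- matrix(g$y, grid_n, grid_n)
  angs <- (s$angle_start + (seq_len(n_ang) - 1) * s$angle_step_deg) * pi / 180
  acc <- matrix(0, grid_n, grid_n)
  for (a in seq_len(n_ang)) {
    ct <- cos(angs[a]); st <- sin(angs[a])
    if (geom$beam == "fan_flat") {
      lpar <- sod + X * ct + Y * st         # distance along central axis
      sloc <- sod * (-X * st + Y * ct) / lpar
      U2 <- (lpar / sod)^2
    } else {
      sloc <- -X * st + Y * ct
      U2 <- 1
    }
    kf <- sloc / pitch_iso + (geom$det_count + 1) / 2
    k0 <- floor(kf); fk <- kf - k0
    row <- filt[a, ]
    pickr <- function(k) {
      ok <- k >= 1 & k <= geom$det_count
      v <- numeric(length(k)); v[ok] <- row[k[ok]]; v
    }
    q <- (1 - fk) * pickr(as.vector(k0)) + fk * pickr(as.vector(k0 + 1))
    acc <- acc + matrix(q, grid_n, grid_n) / U2
  }
  dtheta <- s$angle_step_deg * pi / 180
  scale <- if (n_ang * s$angle_step_deg > 180 + 1e-9) dtheta / 2 else dtheta
  slice_image(acc * scale, voxel_mm)
}
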