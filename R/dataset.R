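#' Paper-style study geometry scaled to a desk-size detector row
#'
#' The flat-panel micro-CT geometry (SOD 299 mm, SID 325 mm, 75 um pitch)
#' with a configurable number of detector bins; the matched reconstruction
#' grid uses the demagnified pitch scaled so the grid spans `fill` of the
#' detector field of view.
#'
#' @param det_count Detector bins.
#' @param grid_n Reconstruction grid side (pixels).
#' @param fill Fraction of the FOV spanned by the grid (default 0.9).
#' @param beam Beam type.
#' @return List with `geometry` ([scan_geometry()]) and `voxel_mm`.
#' @export
study_geometry <- function(det_count = 192, grid_n = 128, fill = 0.9,
                           beam = "fan_flat") {
  geom <- scan_geometry(299, 325, 75, det_count, beam = beam)
  voxel_mm <- isocenter_voxel_size(geom) / 1000 * det_count / grid_n * fill
  list(geometry = geom, voxel_mm = voxel_mm)
}

# random thick-stroke/blob phantom standing in for handwritten-digit shapes
digit_like_phantom <- function(grid_n, voxel_mm = 0.069) {
  k <- sample(2:4, 1)
  img <- matrix(0, grid_n, grid_n)
  cc <- seq_len(grid_n)
  X <- matrix(cc, grid_n, grid_n, byrow = TRUE)
  Y <- matrix(cc, grid_n, grid_n)
  lo <- grid_n * 0.2; hi <- grid_n * 0.8
  for (i in seq_len(k)) {
    mu <- stats::runif(1, 0.01, 0.05)
    thick <- stats::runif(1, grid_n / 40, grid_n / 16)
    if (stats::runif(1) < 0.5) {  # stroke: distance to a segment
      p1 <- stats::runif(2, lo, hi); p2 <- stats::runif(2, lo, hi)
      v <- p2 - p1; L2 <- sum(v^2)
      t <- ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / max(L2, 1)
      t <- pmin(pmax(t, 0), 1)
      d2 <- (X - (p1[1] + t * v[1]))^2 + (Y - (p1[2] + t * v[2]))^2
      img[d2 <= thick^2] <- mu
    } else {                      # ring blob
      c0 <- stats::runif(2, lo, hi); r0 <- stats::runif(1, grid_n / 12, grid_n / 5)
      d <- sqrt((X - c0[1])^2 + (Y - c0[2])^2)
      img[abs(d - r0) <= thick] <- mu
    }
  }
  slice_image(img, voxel_mm)
}

#' Generate a paired limited-angle training/testing dataset
#'
#' For each slice a randomised phantom is drawn (cylinders, Shepp-Logan pose
#' variants, or digit-like strokes), pose-augmented (rotation, reflection,
#' reversed angular ordering), forward-projected over 360 degrees, extended
#' to the 450-degree reference sinogram, optionally resampled to the
#' context-encoder dimensions, and masked over the `[90, 360)` band. Each
#' sample records its own seed, so regeneration from `(config, master seed)`
#' is bit-reproducible.
#'
#' @param n_slices Number of phantom slices.
#' @param kind `"cylinders"`, `"shepp_logan"` or `"digit_like"`.
#' @param grid_n Phantom grid side.
#' @param det_count Detector bins (also the sinogram radial dimension before
#'   any resize).
#' @param step_deg Angular step of the simulated full rotation.
#' @param cfg A [cylinder_config()] (randomisation and pose switches).
#' @param arch Optional [ce_architecture()]; when given, the complete and
#'   masked sinograms are resampled to its input dimensions.
#' @param noise `"none"` (default) or `"poisson"` (transmission counts at
#'   `i0` photons per ray).
#' @param i0 Incident photon count for the Poisson switch.
#' @param seed Master seed.
#' @return A `ce_dataset`: list with `samples` (each
#'   `list(complete, masked, mask, seed)`), `value_range`, and the generating
#'   configuration.
#' @export
generate_dataset <- function(n_slices, kind = c("cylinders", "shepp_logan", "digit_like"),
                             grid_n = 96, det_count = 176, step_deg = 2.5,
                             cfg = cylinder_config(), arch = NULL,
                             noise = c("none", "poisson"), i0 = 1e5, seed = 1) {
  kind <- match.arg(kind); noise <- match.arg(noise)
  # fill 0.7 keeps the whole grid square (diagonal included) inside the fan
  # FOV, so no training phantom is ever truncated in any view
  sg <- study_geometry(det_count, grid_n, fill = 0.7)
  protocol <- acquisition_protocol(step_deg, 360)
  sm <- build_system_matrix(sg$geometry, grid_n, projection_angles(protocol),
                            voxel_mm = sg$voxel_mm)
  base_sl <- if (kind == "shepp_logan") {
    sl <- shepp_logan(grid_n, voxel_mm = sg$voxel_mm)
    # head phantom values (0..2) scaled to tissue-like attenuation
    slice_image(as_matrix_any(sl) * 0.025, sg$voxel_mm)
  } else NULL
  samples <- vector("list", n_slices)
  vmax <- 0
  for (i in seq_len(n_slices)) {
    seed_i <- seed + i
    samples[[i]] <- with_seed(seed_i, {
      ph <- switch(kind,
        cylinders = random_cylinder_phantom(grid_n, cfg, sg$voxel_mm),
        shepp_logan = base_sl,
        digit_like = digit_like_phantom(grid_n, sg$voxel_mm))
      ph <- randomize_pose(ph, cfg)
      p360 <- forward_project(ph, sm)
      if (isTRUE(attr(ph, "reversed_rotation")))
        p360$values <- p360$values[rev(seq_len(nrow(p360$values))), , drop = FALSE]
      if (noise == "poisson") {
        counts <- stats::rpois(length(p360$values), i0 * exp(-pmin(p360$values, 30)))
        p360$values <- matrix(-log(pmax(counts, 0.5) / i0), nrow(p360$values))
      }
      s450 <- extend_to_450(p360)
      s450$known <- rep(TRUE, nrow(s450$values))
      la <- apply_la_mask(s450)
      complete <- s450; masked <- la$sinogram
      if (!is.null(arch)) {
        complete <- resize_for_ce(complete, arch$angles, arch$bins)
        masked <- resize_for_ce(masked, arch$angles, arch$bins)
      }
      list(complete = complete, masked = masked,
           mask = masked$known, seed = seed_i)
    })
    vmax <- max(vmax, max(samples[[i]]$complete$values))
  }
  structure(list(samples = samples, value_range = c(0, vmax),
                 kind = kind, grid_n = grid_n, det_count = det_count,
                 step_deg = step_deg, cfg = cfg, noise = noise,
                 master_seed = seed,
                 geometry = sg$geometry, voxel_mm = sg$voxel_mm),
            class = "ce_dataset")
}

print.ce_dataset <- function(x, ...) {
  d <- dim(x$samples[[1]]$complete$values)
  cat(sprintf("<ce_dataset> %d %s slices, sinograms %d x %d, value range [0, %.3g]\n",
              length(x$samples), x$kind, d[1], d[2], x$value_range[2]))
  invisible(x)
}
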