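#' Randomisation settings for the Monte-Carlo cylinder phantoms
#'
#' Training/testing phantoms are filled discs ("cylinders" seen end-on) with
#' randomised count, position, radius and pose. Defaults follow the generation
#' rules of the study design: 1-4 cylinders with radii uniform in 10-20 px,
#' random initial rotation, optional reflection and reversed rotation.
#' Disc attenuation values are drawn uniform in `value_range`
#' (soft-tissue-like at ~60 kVp).
#'
#' @param n_cyl_range Integer pair, inclusive range of the number of discs.
#' @param radius_range_px Integer pair, inclusive disc radius range in pixels.
#' @param value_range Attenuation range (1/mm) for the disc values.
#' @param allow_reflection,allow_reversed_rotation Enable the pose switches.
#' @param rotation_max_deg Upper bound of the uniform initial rotation.
#' @return A `cylinder_config` list.
#' @export
cylinder_config <- function(n_cyl_range = c(1L, 4L),
                            radius_range_px = c(10L, 20L),
                            value_range = c(0.01, 0.05),
                            allow_reflection = TRUE,
                            allow_reversed_rotation = TRUE,
                            rotation_max_deg = 360) {
  if (n_cyl_range[1] < 1L || n_cyl_range[2] < n_cyl_range[1])
    stop("configuration error: need 1 <= n_cyl_min <= n_cyl_max", call. = FALSE)
  if (radius_range_px[1] <= 0 || radius_range_px[2] < radius_range_px[1])
    stop("configuration error: radius bounds must be positive and ordered", call. = FALSE)
  structure(list(n_cyl_range = as.integer(n_cyl_range),
                 radius_range_px = radius_range_px,
                 value_range = value_range,
                 allow_reflection = isTRUE(allow_reflection),
                 allow_reversed_rotation = isTRUE(allow_reversed_rotation),
                 rotation_max_deg = rotation_max_deg),
            class = "cylinder_config")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded draws never perturb the surrounding random stream. A `NULL` seed
#' evaluates `code` on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Random cylinder phantom
#'
#' Draws `k` in `n_cyl_range` filled discs with radii uniform in
#' `radius_range_px` and centres uniform over positions that keep each disc
#' fully inside the grid. Discs are drawn in order, later discs overwriting
#' earlier ones where they overlap; the background is 0.
#'
#' @param grid_n Image side length in pixels (>= 16).
#' @param cfg A [cylinder_config()].
#' @param voxel_mm Voxel size (mm) recorded in the output image.
#' @param seed Optional integer seed making the draw reproducible; when `NULL`
#'   the current RNG stream is used.
#' @return A [slice_image()].
#' @export
random_cylinder_phantom <- function(grid_n, cfg = cylinder_config(),
                                    voxel_mm = 0.069, seed = NULL) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 16L) stop("'grid_n' must be >= 16", call. = FALSE)
  rmax <- max(cfg$radius_range_px)
  if (2 * rmax >= grid_n)
    stop("configuration error: maximum radius does not fit in the grid", call. = FALSE)
  with_seed(seed, {
    k <- sample(seq(cfg$n_cyl_range[1], cfg$n_cyl_range[2]), 1L)
    img <- matrix(0, grid_n, grid_n)
    cc <- seq_len(grid_n)
    for (i in seq_len(k)) {
      r <- stats::runif(1, cfg$radius_range_px[1], cfg$radius_range_px[2])
      cx <- stats::runif(1, r + 1, grid_n - r)
      cy <- stats::runif(1, r + 1, grid_n - r)
      mu <- stats::runif(1, cfg$value_range[1], cfg$value_range[2])
      d2 <- outer((cc - cy)^2, (cc - cx)^2, `+`)
      img[d2 <= r^2] <- mu
    }
    slice_image(img, voxel_mm)
  })
}

# Head phantom ellipse table: value, semi-axes a (x), b (y), c (z),
# centre (x0, y0, z0), rotation phi (deg, about z). Values sum to [0, 2].
shepp_logan_table <- function() {
  m <- rbind(
    c( 2.00, 0.6900, 0.920, 0.810,  0.00,  0.0000,  0.00,   0),
    c(-0.98, 0.6624, 0.874, 0.780,  0.00, -0.0184,  0.00,   0),
    c(-0.02, 0.1100, 0.310, 0.220,  0.22,  0.0000,  0.00, -18),
    c(-0.02, 0.1600, 0.410, 0.280, -0.22,  0.0000,  0.00,  18),
    c( 0.01, 0.2100, 0.250, 0.410,  0.00,  0.3500, -0.15,   0),
    c( 0.01, 0.0460, 0.046, 0.050,  0.00,  0.1000,  0.25,   0),
    c( 0.01, 0.0460, 0.046, 0.050,  0.00, -0.1000,  0.25,   0),
    c( 0.01, 0.0460, 0.023, 0.050, -0.08, -0.6050,  0.00,   0),
    c( 0.01, 0.0230, 0.023, 0.020,  0.00, -0.6060,  0.00,   0),
    c( 0.01, 0.0230, 0.046, 0.020,  0.06, -0.6050,  0.00,   0))
  colnames(m) <- c("A", "a", "b", "c", "x0", "y0", "z0", "phi")
  m
}

#' Shepp-Logan head phantom
#'
#' The classic 10-ellipse head phantom on the unit square (2D) or its
#' ellipsoid extension on the unit cube (3D), sampled at `grid_n` pixels per
#' side. Values are sums of the component intensities and lie in `[0, 2]`.
#'
#' @param grid_n Pixels per side (>= 16).
#' @param dims 2 for a slice, 3 for a volume.
#' @param voxel_mm Voxel size recorded in the output.
#' @param oversample Sub-pixel sampling factor per axis for the 2D phantom
#'   (area-weighted pixelation of the continuous ellipses; 1 gives hard
#'   binary-membership edges).
#' @return A [slice_image()] (`dims = 2`) or [volume_image()] (`dims = 3`).
#' @export
shepp_logan <- function(grid_n, dims = 2, voxel_mm = 2 / grid_n, oversample = 4) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 16L) stop("'grid_n' must be >= 16", call. = FALSE)
  stopifnot(dims %in% c(2, 3), oversample >= 1)
  tab <- shepp_logan_table()
  idx <- seq_len(grid_n)
  x <- (idx - (grid_n + 1) / 2) * (2 / grid_n)
  y <- rev(x)  # row index runs down, +y up
  if (dims == 2) {
    os <- as.integer(oversample)
    nf <- grid_n * os
    xf <- (seq_len(nf) - (nf + 1) / 2) * (2 / nf)
    yf <- rev(xf)
    img <- matrix(0, nf, nf)
    X <- matrix(xf, nf, nf, byrow = TRUE)
    Y <- matrix(yf, nf, nf)
    for (e in seq_len(nrow(tab))) {
      p <- tab[e, ]
      ct <- cospi(p["phi"] / 180); st <- sinpi(p["phi"] / 180)
      xr <- (X - p["x0"]) * ct + (Y - p["y0"]) * st
      yr <- -(X - p["x0"]) * st + (Y - p["y0"]) * ct
      img <- img + p["A"] * ((xr / p["a"])^2 + (yr / p["b"])^2 <= 1)
    }
    if (os > 1L) {  # block-average back to grid_n (area weighting)
      img <- matrix(colMeans(matrix(img, nrow = os)), nrow = grid_n)      # rows
      img <- t(matrix(colMeans(matrix(t(img), nrow = os)), nrow = grid_n)) # cols
    }
    slice_image(pmax(img, 0), voxel_mm)
  } else {
    vol <- array(0, c(grid_n, grid_n, grid_n))
    z <- x
    X <- matrix(x, grid_n, grid_n, byrow = TRUE)
    Y <- matrix(y, grid_n, grid_n)
    for (k in idx) {
      sl <- matrix(0, grid_n, grid_n)
      for (e in seq_len(nrow(tab))) {
        p <- tab[e, ]
        zz <- (z[k] - p["z0"]) / p["c"]
        if (abs(zz) >= 1) next
        ct <- cospi(p["phi"] / 180); st <- sinpi(p["phi"] / 180)
        xr <- (X - p["x0"]) * ct + (Y - p["y0"]) * st
        yr <- -(X - p["x0"]) * st + (Y - p["y0"]) * ct
        sl <- sl + p["A"] * ((xr / p["a"])^2 + (yr / p["b"])^2 <= 1 - zz^2)
      }
      vol[, , k] <- sl
    }
    volume_image(pmax(vol, 0), voxel_mm)
  }
}

#' Rotate a square image about its centre (bilinear, zero fill)
#'
#' @param img Matrix or [slice_image()].
#' @param deg Counter-clockwise rotation in degrees. Multiples of 90 use exact
#'   trigonometric values.
#' @return Rotated object of the same type.
#' @export
rotate_image <- function(img, deg) {
  n <- nrow(img)
  stopifnot(n == ncol(img))
  ct <- cospi(deg / 180); st <- sinpi(deg / 180)
  idx <- seq_len(n)
  cx <- (n + 1) / 2
  X <- matrix(idx - cx, n, n, byrow = TRUE)   # +x right (columns)
  Y <- matrix(cx - idx, n, n)                 # +y up (rows down)
  # inverse map: source coords = R(-deg) . (x, y)
  xs <- ct * X + st * Y
  ys <- -st * X + ct * Y
  colf <- xs + cx
  rowf <- cx - ys
  r0 <- floor(rowf); c0 <- floor(colf)
  fr <- rowf - r0; fc <- colf - c0
  m <- as_matrix_any(img)
  pick <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= n
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- (1 - frv) * (1 - fcv) * pick(r0v, c0v) +
         (1 - frv) * fcv       * pick(r0v, c0v + 1) +
         frv       * (1 - fcv) * pick(r0v + 1, c0v) +
         frv       * fcv       * pick(r0v + 1, c0v + 1)
  out <- matrix(out, n, n)
  if (inherits(img, "slice_image")) slice_image(out, voxel_size_mm(img)) else out
}

as_matrix_any <- function(x) matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))

#' Random pose augmentation: rotation, reflection, reversed rotation
#'
#' Applies a random initial rotation (bilinear, zero fill) and an optional
#' left-right reflection, and records a `reversed_rotation` attribute that
#' sinogram generation consumes by negating the angular ordering of the rows.
#'
#' @param img A [slice_image()] (square).
#' @param cfg A [cylinder_config()] providing the pose switches.
#' @param seed Optional integer seed.
#' @param rotation_deg,reflect,reverse Explicit overrides; when `NULL` they are
#'   drawn at random per `cfg`.
#' @return The transformed [slice_image()] with attributes `rotation_deg`,
#'   `reflected` and `reversed_rotation`.
#' @export
randomize_pose <- function(img, cfg = cylinder_config(), seed = NULL,
                           rotation_deg = NULL, reflect = NULL, reverse = NULL) {
  stopifnot(nrow(img) == ncol(img))
  with_seed(seed, {
    if (is.null(rotation_deg)) rotation_deg <- stats::runif(1, 0, cfg$rotation_max_deg)
    if (is.null(reflect))
      reflect <- cfg$allow_reflection && stats::runif(1) < 0.5
    if (is.null(reverse))
      reverse <- cfg$allow_reversed_rotation && stats::runif(1) < 0.5
    out <- if (rotation_deg != 0) rotate_image(img, rotation_deg) else img
    if (reflect) {
      m <- as_matrix_any(out)[, rev(seq_len(ncol(out)))]
      out <- slice_image(m, voxel_size_mm(img))
    }
    attr(out, "rotation_deg") <- rotation_deg
    attr(out, "reflected") <- reflect
    attr(out, "reversed_rotation") <- reverse
    out
  })
}

disc_mask <- function(grid_n, voxel_mm, cx_mm, cy_mm, r_mm) {
  g <- grid_coords(grid_n, voxel_mm)
  outer((g$y - cy_mm)^2, (g$x - cx_mm)^2, `+`) <= r_mm^2
}

#' Digital quality-assurance phantoms
#'
#' Four QA layouts used for figure-of-merit measurements:
#' \describe{
#'   \item{`qa_wire`}{two thin-wire impulses of identical integrated mass, one
#'     at the centre and one peripheral, each annotated with a horizontal
#'     profile line for FWHM measurement;}
#'   \item{`qa_contrast`}{a water disc with a dense core and the five-ROI
#'     layout (centre core plus upper/lower/left/right background ROIs) for
#'     CNR;}
#'   \item{`qa_water`}{a uniform water disc with five square ROIs for SNR;}
#'   \item{`qa_ha`}{a water disc with five hydroxyapatite inserts of nominal
#'     densities `ha_densities` (mg/cm^3) and matching ROIs for linearity.}
#' }
#'
#' @param kind One of `"qa_wire"`, `"qa_contrast"`, `"qa_water"`, `"qa_ha"`.
#' @param grid_n Pixels per side.
#' @param voxel_um Voxel size in micrometres.
#' @param roi_mm ROI side length in mm (default the standard 3 mm).
#' @param ha_densities Nominal insert densities, mg/cm^3.
#' @param wire_offset_frac Peripheral wire offset as a fraction of the grid
#'   half-width.
#' @return List with elements `image` ([slice_image()]), `rois` (list of
#'   [roi_spec()]), `lines` (list of [profile_line()], wire only), and for
#'   `qa_ha` the `densities` vector.
#' @export
qa_phantom <- function(kind = c("qa_wire", "qa_contrast", "qa_water", "qa_ha"),
                       grid_n = 128, voxel_um = 138, roi_mm = 3,
                       ha_densities = c(0, 50, 200, 800, 1200),
                       wire_offset_frac = 0.6) {
  kind <- match.arg(kind)
  voxel_mm <- voxel_um / 1000
  half_mm <- grid_n * voxel_mm / 2
  mu_water <- 0.02
  img <- matrix(0, grid_n, grid_n)
  rois <- list(); lines <- list(); densities <- NULL

  check_roi <- function(roi) {
    if (abs(roi$center_mm[1]) + roi$width_mm / 2 > half_mm ||
        abs(roi$center_mm[2]) + roi$height_mm / 2 > half_mm)
      stop("configuration error: ROI exceeds image bounds", call. = FALSE)
    roi
  }
  five_rois <- function(offset_mm, role_center = "signal", role_ring = "background") {
    cen <- list(c(0, 0), c(0, offset_mm), c(0, -offset_mm),
                c(-offset_mm, 0), c(offset_mm, 0))
    roles <- c(role_center, rep(role_ring, 4))
    Map(function(cc, role) check_roi(roi_spec(cc, roi_mm, roi_mm, role)), cen, roles)
  }

  if (kind == "qa_wire") {
    # sub-pixel impulses splatted bilinearly so both wires carry equal mass
    splat <- function(img, x_mm, y_mm, mass = 1) {
      g <- grid_coords(grid_n, voxel_mm)
      cf <- (x_mm / voxel_mm) + (grid_n + 1) / 2
      rf <- (grid_n + 1) / 2 - (y_mm / voxel_mm)
      r0 <- floor(rf); c0 <- floor(cf); fr <- rf - r0; fc <- cf - c0
      w <- c((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
      rr <- c(r0, r0, r0 + 1, r0 + 1); cc <- c(c0, c0 + 1, c0, c0 + 1)
      for (i in 1:4) img[rr[i], cc[i]] <- img[rr[i], cc[i]] + mass * w[i]
      img
    }
    xo <- wire_offset_frac * half_mm
    img <- splat(img, 0, 0)
    img <- splat(img, xo, 0)
    hw <- min(2, half_mm / 4)
    lines <- list(profile_line(c(-hw, 0), c(hw, 0), 201),
                  profile_line(c(xo - hw, 0), c(xo + hw, 0), 201))
  } else if (kind == "qa_contrast") {
    # dense core sized to cover the central ROI (incl. its diagonal), ring
    # ROIs fully in the water annulus
    core_r <- 0.75 * roi_mm          # covers the central ROI diagonal (2.12 mm)
    off <- max(0.55 * half_mm, core_r + 0.71 * roi_mm + 0.1 * roi_mm)
    img[disc_mask(grid_n, voxel_mm, 0, 0, 0.85 * half_mm)] <- mu_water
    img[disc_mask(grid_n, voxel_mm, 0, 0, core_r)] <- 0.06
    rois <- five_rois(off)
  } else if (kind == "qa_water") {
    img[disc_mask(grid_n, voxel_mm, 0, 0, 0.85 * half_mm)] <- mu_water
    rois <- five_rois(0.55 * half_mm, role_center = "signal", role_ring = "signal")
  } else { # qa_ha
    img[disc_mask(grid_n, voxel_mm, 0, 0, 0.85 * half_mm)] <- mu_water
    densities <- ha_densities
    # mu rises linearly with HA density (~2e-5 mm^-1 per mg/cm^3 at ~60 kVp);
    # insert radius covers the ROI diagonal, spacing keeps inserts disjoint
    ins_r <- 0.75 * roi_mm
    off <- max(0.55 * half_mm, 2.05 * ins_r)
    cen <- list(c(0, 0), c(0, off), c(off, 0), c(0, -off), c(-off, 0))
    rois <- vector("list", 5)
    for (i in seq_len(5)) {
      mu <- mu_water + 2e-5 * densities[i]
      img[disc_mask(grid_n, voxel_mm, cen[[i]][1], cen[[i]][2], ins_r)] <- mu
      rois[[i]] <- check_roi(roi_spec(cen[[i]], roi_mm, roi_mm, "insert"))
    }
  }
  out <- list(kind = kind, image = slice_image(img, voxel_mm), rois = rois,
              lines = lines)
  if (!is.null(densities)) out$densities <- densities
  out
}
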