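#' Rectangular region of interest in physical coordinates
#'
#' @param center_mm Numeric `(x, y)` centre in mm (origin at grid centre).
#' @param width_mm,height_mm ROI extents in mm (default the standard 3 mm).
#' @param role `"signal"`, `"background"` or `"insert"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_mm, width_mm = 3, height_mm = width_mm,
                     role = c("signal", "background", "insert")) {
  role <- match.arg(role)
  stopifnot(length(center_mm) == 2, width_mm > 0, height_mm > 0)
  structure(list(center_mm = as.numeric(center_mm), width_mm = width_mm,
                 height_mm = height_mm, role = role), class = "roi_spec")
}

#' ROI pixel statistics
#'
#' Pixels whose centres fall inside the ROI rectangle contribute.
#'
#' @param img A [slice_image()].
#' @param roi A [roi_spec()].
#' @return List with `mean`, `sd` (sample SD) and `n` pixels.
#' @export
roi_stats <- function(img, roi) {
  stopifnot(inherits(img, "slice_image"), inherits(roi, "roi_spec"))
  g <- grid_coords(nrow(img), voxel_size_mm(img))
  cx <- roi$center_mm[1]; cy <- roi$center_mm[2]
  cols <- which(abs(g$x - cx) <= roi$width_mm / 2)
  rows <- which(abs(g$y - cy) <= roi$height_mm / 2)
  if (!length(rows) || !length(cols))
    stop("ROI contains no pixel centres", call. = FALSE)
  v <- as_matrix_any(img)[rows, cols]
  list(mean = mean(v), sd = stats::sd(as.vector(v)), n = length(v))
}

#' Straight profile line through an image
#'
#' @param start_mm,end_mm Numeric `(x, y)` endpoints in mm.
#' @param n Number of samples along the line.
#' @return An object of class `profile_line`.
#' @export
profile_line <- function(start_mm, end_mm, n = 200) {
  stopifnot(length(start_mm) == 2, length(end_mm) == 2, n >= 2)
  if (sum((end_mm - start_mm)^2) == 0)
    stop("profile line has zero length", call. = FALSE)
  structure(list(start_mm = as.numeric(start_mm), end_mm = as.numeric(end_mm),
                 n = as.integer(n)), class = "profile_line")
}

#' Sample image values along a profile line (bilinear)
#'
#' @param img A [slice_image()].
#' @param line A [profile_line()].
#' @return List with `pos_mm` (distance along the line) and `values`.
#' @export
sample_profile <- function(img, line) {
  stopifnot(inherits(img, "slice_image"), inherits(line, "profile_line"))
  n <- nrow(img); h <- voxel_size_mm(img)
  t <- seq(0, 1, length.out = line$n)
  xs <- line$start_mm[1] + t * (line$end_mm[1] - line$start_mm[1])
  ys <- line$start_mm[2] + t * (line$end_mm[2] - line$start_mm[2])
  cf <- xs / h + (n + 1) / 2
  rf <- (n + 1) / 2 - ys / h
  m <- as_matrix_any(img)
  r0 <- floor(rf); c0 <- floor(cf); fr <- rf - r0; fc <- cf - c0
  pick <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= n
    v <- numeric(length(r)); v[ok] <- m[cbind(r[ok], c[ok])]; v
  }
  vals <- (1 - fr) * (1 - fc) * pick(r0, c0) + (1 - fr) * fc * pick(r0, c0 + 1) +
          fr * (1 - fc) * pick(r0 + 1, c0) + fr * fc * pick(r0 + 1, c0 + 1)
  list(pos_mm = t * sqrt(sum((line$end_mm - line$start_mm)^2)), values = vals)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `psnr` uses the joint maximum pixel value over both images as the peak, so
#' identical images give `Inf` (a defined sentinel, not an error).
#'
#' @param f1,f2 Images or numeric arrays of equal shape.
#' @return `mse`: mean of squared differences. `psnr`: value in dB.
#' @export
mse <- function(f1, f2) {
  if (!identical(dim(f1), dim(f2)) || length(f1) != length(f2))
    stop("shape mismatch", call. = FALSE)
  mean((as.numeric(f1) - as.numeric(f2))^2)
}

#' @rdname mse
#' @export
psnr <- function(f1, f2) {
  m <- mse(f1, f2)
  if (m == 0) return(Inf)
  peak <- max(max(f1), max(f2))
  10 * log10(peak^2 / m)
}

#' Universal image quality index
#'
#' Global-statistics UIQI
#' `4 mu1 mu2 sigma12 / ((mu1^2 + mu2^2)(sigma1^2 + sigma2^2))`, computed as
#' the product of its correlation, luminance and contrast factors so that
#' degenerate factors (0/0) drop out as 1. Equals 1 only for identical
#' non-constant images; two constant zero images give `NaN`.
#'
#' @param f1,f2 Images of equal shape.
#' @return Scalar in `[-1, 1]` (or `NaN` when fully degenerate).
#' @export
uiqi <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("shape mismatch", call. = FALSE)
  x <- as.numeric(f1); y <- as.numeric(f2)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  sxy <- stats::cov(x, y)
  # means at floating-point noise level relative to the spread count as zero,
  # so the luminance factor drops out instead of amplifying roundoff
  m2 <- mx^2 + my^2
  zero_mean <- m2 <= 1e-20 * (vx + vy)
  lum <- if (m2 > 0 && !zero_mean) 2 * mx * my / m2 else 1
  con <- if (vx + vy > 0) 2 * sqrt(vx * vy) / (vx + vy) else 1
  cor_ <- if (vx > 0 && vy > 0) sxy / sqrt(vx * vy) else if (vx + vy == 0) 1 else 0
  if (m2 == 0 && vx + vy == 0) return(NaN)
  lum * con * cor_
}

# separable "valid" convolution with a 1D kernel (shift-and-add, vectorised)
conv2_valid <- function(m, k) {
  kl <- length(k)
  nr <- nrow(m) - kl + 1; nc <- ncol(m)
  a <- matrix(0, nr, nc)
  for (i in seq_len(kl)) a <- a + k[i] * m[i:(i + nr - 1), , drop = FALSE]
  out <- matrix(0, nr, nc - kl + 1)
  for (i in seq_len(kl)) out <- out + k[i] * a[, i:(i + ncol(out) - 1), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' `mode = "gaussian"` (default) uses the conventional 11x11 Gaussian window
#' with sigma 1.5, mean-pooled over the valid region. `mode = "global"`
#' evaluates the SSIM formula once on whole-image statistics. Regularisers are
#' `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`.
#'
#' @param f1,f2 Images of equal shape.
#' @param L Dynamic range of the data (must be > 0).
#' @param mode `"gaussian"` or `"global"`.
#' @return SSIM scalar.
#' @export
ssim <- function(f1, f2, L = max(max(f1), max(f2)) - min(min(f1), min(f2)),
                 mode = c("gaussian", "global")) {
  mode <- match.arg(mode)
  if (!identical(dim(f1), dim(f2))) stop("shape mismatch", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  x <- as_matrix_any(f1); y <- as_matrix_any(f2)
  if (mode == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
    sxy <- stats::cov(as.vector(x), as.vector(y))
    return(((2 * mx * my + c1) * (2 * sxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (min(dim(x)) < 11)
    stop("image smaller than the 11x11 SSIM window; use mode = 'global'", call. = FALSE)
  g <- exp(-((-5:5)^2) / (2 * 1.5^2)); g <- g / sum(g)
  mu1 <- conv2_valid(x, g); mu2 <- conv2_valid(y, g)
  s11 <- conv2_valid(x * x, g) - mu1^2
  s22 <- conv2_valid(y * y, g) - mu2^2
  s12 <- conv2_valid(x * y, g) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(map)
}

#' Relative total variation
#'
#' Ratio of the TV norms of a reconstruction and a reference image; 1 when
#' the edge content ("shape") matches.
#'
#' @param f_star Reconstruction image.
#' @param f_ref Reference image with nonzero TV norm.
#' @return Scalar ratio.
#' @export
rtv <- function(f_star, f_ref) {
  tvr <- tv_norm(f_ref)
  if (tvr == 0) stop("reference image has zero TV norm", call. = FALSE)
  tv_norm(f_star) / tvr
}

#' Contrast-to-noise and signal-to-noise ratios from ROIs
#'
#' `CNR = |mu_sig - mu_bg| / sqrt(sd_sig^2 + sd_bg^2)`; `SNR = mu / sd`
#' (with `Inf` as the defined sentinel for a zero-SD ROI).
#'
#' @param img A [slice_image()].
#' @param roi_sig,roi_bg,roi [roi_spec()] regions.
#' @return Scalar ratio.
#' @export
cnr <- function(img, roi_sig, roi_bg) {
  s <- roi_stats(img, roi_sig); b <- roi_stats(img, roi_bg)
  abs(s$mean - b$mean) / sqrt(s$sd^2 + b$sd^2)
}

#' @rdname cnr
#' @export
snr <- function(img, roi) {
  s <- roi_stats(img, roi)
  if (s$sd == 0) return(Inf)
  s$mean / s$sd
}

#' Full width at half maximum of a peaked profile
#'
#' Least-squares fit of a Gaussian plus constant baseline,
#' `y = b + A exp(-(x - x0)^2 / (2 sigma^2))`; the FWHM is
#' `2 sqrt(2 ln 2) sigma`, in the units of `pos`.
#'
#' @param profile List with `pos` (or `pos_mm`) and `values`, e.g. from
#'   [sample_profile()].
#' @return List with `fwhm`, `sigma`, `center`, `amplitude`, `baseline`.
#' @export
fwhm <- function(profile) {
  pos <- if (!is.null(profile$pos)) profile$pos else profile$pos_mm
  y <- profile$values
  stopifnot(length(pos) == length(y), length(y) >= 5)
  b0 <- min(y); a0 <- max(y) - b0; x0 <- pos[which.max(y)]
  above <- pos[y - b0 > a0 / 2]
  s0 <- max((max(above) - min(above)) / 2.3548, diff(range(pos)) / 50)
  step <- stats::median(diff(pos))
  fit1 <- function(m0, s_init) minpack.lm::nlsLM(
    y ~ b + a * exp(-(pos - x0)^2 / (2 * s^2)),
    start = list(b = b0, a = a0, x0 = m0, s = s_init),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  # a start exactly on a symmetric peak can make the Jacobian singular;
  # retry from a slightly offset centre before giving up
  fit <- tryCatch(fit1(x0, s0), error = function(e)
    tryCatch(fit1(x0 + 0.25 * step, 1.3 * s0), error = function(e2)
      stop("FWHM fit failed to converge: ", conditionMessage(e2),
           call. = FALSE)))
  cf <- stats::coef(fit)
  sigma <- abs(unname(cf["s"]))
  list(fwhm = 2 * sqrt(2 * log(2)) * sigma, sigma = sigma,
       center = unname(cf["x0"]), amplitude = unname(cf["a"]),
       baseline = unname(cf["b"]))
}

#' ROI linearity against nominal insert densities
#'
#' Pearson correlation between measured ROI mean intensities and the inserts'
#' nominal densities.
#'
#' @param img A [slice_image()].
#' @param rois List of [roi_spec()] (>= 3).
#' @param densities Nominal densities, same length as `rois`.
#' @return Pearson correlation coefficient.
#' @export
linearity <- function(img, rois, densities) {
  stopifnot(length(rois) == length(densities), length(rois) >= 3)
  means <- vapply(rois, function(r) roi_stats(img, r)$mean, numeric(1))
  if (stats::sd(means) == 0 || stats::sd(densities) == 0)
    stop("zero variance in ROI means or densities", call. = FALSE)
  stats::cor(means, densities)
}
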