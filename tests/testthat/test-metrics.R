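test_that("MSE/PSNR reproduce hand-computed cases and the identity sentinel", {
  f1 <- c(0, 1); f2 <- c(0, 0.9)
  expect_equal(mse(f1, f2), 0.005)
  expect_equal(psnr(f1, f2), 23.0103, tolerance = 1e-4)
  expect_equal(psnr(f1, f1), Inf)
  # peak 1, mse 0.01 -> 20 dB
  x <- c(rep(0, 99), 1); y <- x; y[1:99] <- y[1:99] + sqrt(0.01 * 100 / 99)
  expect_equal(psnr(x, y), 20, tolerance = 1e-9)
  expect_equal(psnr(x, y), psnr(y, x))  # symmetry via joint peak
  expect_error(mse(1:4, 1:5), "shape mismatch")
})

test_that("UIQI follows the mean/variance/covariance formula", {
  set.seed(1)
  f <- matrix(runif(400), 20)
  expect_equal(uiqi(f, f), 1.0)
  # constant offset: only the luminance term degrades
  c0 <- 0.7
  m1 <- mean(f); m2 <- m1 + c0
  expect_equal(uiqi(f, f + c0), 2 * m1 * m2 / (m1^2 + m2^2), tolerance = 1e-12)
  expect_lt(uiqi(f, f + c0), 1)
  # zero-mean sign flip gives -1
  z <- f - mean(f)
  expect_equal(uiqi(z, -z), -1.0)
  # bounded above by 1 for random pairs
  for (i in 1:20) {
    a <- rnorm(100); b <- rnorm(100)
    expect_lte(uiqi(a, b), 1)
  }
  expect_true(is.nan(uiqi(numeric(9), numeric(9))))
})

test_that("SSIM constants, identity and constant-image saturation are exact", {
  set.seed(2)
  f <- matrix(runif(26^2), 26)
  expect_equal(ssim(f, f), 1.0)
  expect_equal(ssim(f, f, mode = "global"), 1.0)
  # L = 1 constants
  c1 <- (0.01 * 1)^2; c2 <- (0.03 * 1)^2
  expect_equal(c1, 1e-4); expect_equal(c2, 9e-4)
  # two constant images differing by d: contrast/structure saturate
  a <- matrix(0.4, 16, 16); b <- matrix(0.6, 16, 16)
  expect_equal(ssim(a, b, L = 1, mode = "global"),
               (2 * 0.4 * 0.6 + c1) / (0.4^2 + 0.6^2 + c1), tolerance = 1e-12)
  expect_equal(ssim(a, b, L = 1), (2 * 0.4 * 0.6 + c1) / (0.4^2 + 0.6^2 + c1),
               tolerance = 1e-12)
  expect_error(ssim(f, f, L = 0), "positive")
})

test_that("rTV ratio identities hold", {
  set.seed(3)
  f <- matrix(runif(15^2), 15)
  expect_equal(rtv(f, f), 1.0)
  expect_equal(rtv(2 * f, f), 2.0, tolerance = 1e-12)
  # smoothing reduces total variation
  k <- matrix(1 / 9, 3, 3)
  sm <- f
  for (i in 2:14) for (j in 2:14) sm[i, j] <- mean(f[(i - 1):(i + 1), (j - 1):(j + 1)])
  expect_lt(rtv(sm, f), 1)
  expect_error(rtv(f, matrix(1, 5, 5)), "zero TV")
})

test_that("CNR and SNR follow the ROI definitions", {
  # construct an image with two ROIs of known stats
  set.seed(4)
  img <- matrix(0, 60, 60)
  sig <- matrix(rnorm(100, 10, 3), 10); bg <- matrix(rnorm(100, 4, 4), 10)
  img[11:20, 11:20] <- sig; img[41:50, 41:50] <- bg
  im <- slice_image(img, 0.1)
  # ROI rectangles aligned to those blocks (mm coords, origin centre)
  roi_of <- function(r0, c0) {
    g <- (c(r0, c0) + 4.5 - 30.5) * 0.1
    roi_spec(c(g[2], -g[1]), 0.99, 0.99)
  }
  rs <- roi_of(11, 11); rb <- roi_of(41, 41)
  s <- roi_stats(im, rs); b <- roi_stats(im, rb)
  expect_equal(s$n, 100); expect_equal(b$n, 100)
  expect_equal(cnr(im, rs, rb),
               abs(s$mean - b$mean) / sqrt(s$sd^2 + b$sd^2), tolerance = 1e-12)
  expect_equal(snr(im, rs), s$mean / s$sd, tolerance = 1e-12)
  expect_equal(cnr(im, rs, rs), 0)
  # closed-form cases
  expect_equal(abs(10 - 4) / sqrt(3^2 + 4^2), 1.2)
})

test_that("FWHM recovers the generating Gaussian width", {
  x <- seq(0, 200, by = 0.5)
  prof <- list(pos = x, values = 0.2 + 3 * exp(-(x - 90)^2 / (2 * 10^2)))
  fit <- fwhm(prof)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 1e-3)
  expect_equal(fit$fwhm, 23.548, tolerance = 0.001 * 23.548)
  # amplitude scaling leaves FWHM unchanged
  prof2 <- list(pos = x, values = 5 * prof$values)
  expect_equal(fwhm(prof2)$fwhm, fit$fwhm, tolerance = 1e-6)
  # the wire-scan sigma of 21.739 um corresponds to 51.19 um FWHM
  xw <- seq(-150, 150, by = 1)
  w <- list(pos = xw, values = exp(-xw^2 / (2 * 21.739^2)))
  expect_equal(fwhm(w)$fwhm, 51.19, tolerance = 0.01)
})

test_that("linearity equals the Pearson correlation of ROI means vs densities", {
  h <- qa_phantom("qa_ha", grid_n = 128, voxel_um = 138)
  expect_equal(linearity(h$image, h$rois, h$densities), 1.0, tolerance = 1e-9)
  expect_equal(linearity(h$image, h$rois, -h$densities), -1.0, tolerance = 1e-9)
  # direct formula oracle on arbitrary 5-point data
  means <- vapply(h$rois, function(r) roi_stats(h$image, r)$mean, numeric(1))
  d <- c(3, 14, 1, 59, 26)
  r_oracle <- sum((means - mean(means)) * (d - mean(d))) /
    sqrt(sum((means - mean(means))^2) * sum((d - mean(d))^2))
  expect_equal(linearity(h$image, h$rois, d), r_oracle, tolerance = 1e-12)
})

test_that("global metrics are invariant to a joint pixel permutation", {
  set.seed(5)
  a <- matrix(runif(144), 12); b <- matrix(runif(144), 12)
  p <- sample(144)
  ap <- matrix(a[p], 12); bp <- matrix(b[p], 12)
  expect_equal(psnr(a, b), psnr(ap, bp))
  expect_equal(uiqi(a, b), uiqi(ap, bp))
  expect_equal(ssim(a, b, mode = "global"), ssim(ap, bp, mode = "global"))
})
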