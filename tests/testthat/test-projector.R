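test_that("single parallel rays integrate exactly through rows and discs", {
  # one horizontal ray through a grid of pixel size h: every entry equals h
  geom <- fix_geom(33, beam = "parallel")
  vox <- isocenter_voxel_size(geom) / 1000
  sm <- suppressWarnings(build_system_matrix(geom, 33, angles_deg = 0, voxel_mm = vox))
  # central detector bin row: ray along +x through the middle pixel row
  mid_ray <- (33 + 1) / 2
  row <- sm$A[mid_ray, ]
  nz <- row[row != 0]
  expect_length(nz, 33)
  expect_true(all(abs(nz - vox) < 1e-10))

  # row sums equal the chord length through the grid square
  rs <- Matrix::rowSums(sm$A)
  expect_lte(max(rs), 33 * vox * sqrt(2) + 1e-9)
  expect_equal(max(rs), 33 * vox, tolerance = 1e-9)  # axis-aligned chords

  # 45-degree ray through pixel centres: entries h * sqrt(2)
  sm45 <- suppressWarnings(build_system_matrix(geom, 33, angles_deg = 45, voxel_mm = vox))
  d45 <- sm45$A[mid_ray, ]
  nz45 <- d45[d45 != 0]
  expect_true(all(abs(nz45 - vox * sqrt(2)) < 1e-8))

  # central ray through a unit-attenuation disc of radius r: integral 2r
  disc <- fix_disc(33, vox, radius_px = 8, mu = 1)
  p <- forward_project(disc, sm)
  # pixelised disc: pixels with centres inside r span 2r + 1 pixels on axis
  expect_lt(abs(p$values[1, mid_ray] - 2 * 8 * vox), 1.2 * vox)
})

test_that("forward projection equals a dense matrix multiply", {
  geom <- fix_geom(48)
  vox <- fix_grid(geom, 32)
  sm <- build_system_matrix(geom, 32, seq(0, 350, by = 10), voxel_mm = vox)
  set.seed(9)
  f <- matrix(runif(32 * 32), 32)
  p <- forward_project(slice_image(f, vox), sm)
  dense <- as.matrix(sm$A) %*% as.vector(f)
  expect_lt(max(abs(as.vector(t(p$values)) - dense)) / max(abs(dense)), 1e-12)
  expect_true(all(p$values >= 0))
  # zero image projects to zero
  p0 <- forward_project(slice_image(matrix(0, 32, 32), vox), sm)
  expect_equal(sum(abs(p0$values)), 0)
})

test_that("backprojection is the exact adjoint for random geometries", {
  set.seed(10)
  for (beam in c("parallel", "fan_flat")) {
    geom <- fix_geom(40, beam = beam)
    vox <- fix_grid(geom, 24)
    angles <- sort(runif(17, 0, 360))
    sm <- build_system_matrix(geom, 24, angles, voxel_mm = vox, cache = FALSE)
    f <- matrix(runif(24 * 24), 24)
    g <- matrix(runif(17 * 40), 17)
    lhs <- sum(forward_project(slice_image(f, vox), sm)$values * g)
    rhs <- sum(f * unclass(back_project(g, sm)))
    denom <- sqrt(sum(forward_project(slice_image(f, vox), sm)$values^2)) *
      sqrt(sum(g^2))
    expect_lt(abs(lhs - rhs) / denom, 1e-10)
  }
  # zero sinogram backprojects to zero; single-ray support is the ray trace
  geom <- fix_geom(21, beam = "parallel")
  vox <- isocenter_voxel_size(geom) / 1000
  sm <- suppressWarnings(build_system_matrix(geom, 21, 0, voxel_mm = vox))
  z <- back_project(matrix(0, 1, 21), sm)
  expect_equal(sum(abs(z)), 0)
  one <- matrix(0, 1, 21); one[1, 11] <- 1
  bp <- back_project(one, sm)
  expect_equal(which(unclass(bp) != 0), which(as.vector(sm$A[11, ]) != 0))
})

test_that("an off-centre impulse traces a sinusoid across the parallel sinogram", {
  geom <- fix_geom(64, beam = "parallel")
  vox <- isocenter_voxel_size(geom) / 1000
  n <- 64
  img <- matrix(0, n, n)
  r_px <- 18
  img[n / 2 + 1, n / 2 + 1 + r_px] <- 1   # impulse at (x, y) = (r, 0)
  angles <- seq(0, 355, by = 5)
  sm <- suppressWarnings(build_system_matrix(geom, n, angles, voxel_mm = vox))
  p <- forward_project(slice_image(img, vox), sm)
  peak_bin <- apply(p$values, 1, which.max)
  # ray offset of a point at radius r: t = -x sin + y cos -> -r sin(theta)
  expected <- (-r_px) * sinpi(angles / 180) + (geom$det_count + 1) / 2
  expect_lte(max(abs(peak_bin - expected)), 1.6)
})

test_that("fan-beam rows are 360-degree periodic and cache hits return the same object", {
  geom <- fix_geom(40)
  vox <- fix_grid(geom, 24)
  sm <- build_system_matrix(geom, 24, c(10, 370), voxel_mm = vox, cache = FALSE)
  disc <- fix_disc(24, vox, radius_px = 6)
  p <- forward_project(disc, sm)
  expect_lt(max(abs(p$values[1, ] - p$values[2, ])), 1e-12)

  clear_system_matrix_cache()
  s1 <- build_system_matrix(geom, 24, c(0, 90), voxel_mm = vox)
  s2 <- build_system_matrix(geom, 24, c(0, 90), voxel_mm = vox)
  expect_identical(s1$A, s2$A)
  expect_equal(clear_system_matrix_cache(), 1)
})

test_that("an object larger than the FOV triggers the truncation warning", {
  geom <- fix_geom(24)
  vox <- isocenter_voxel_size(geom) / 1000 * 3  # grid much wider than FOV
  expect_warning(build_system_matrix(geom, 32, c(0, 45), voxel_mm = vox,
                                     cache = FALSE),
                 "field of view")
})
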