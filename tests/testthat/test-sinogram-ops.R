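mk_sino <- function(n_ang, n_det, step, seed = 1) {
  set.seed(seed)
  sinogram(matrix(runif(n_ang * n_det), n_ang), step, bin_pitch_um = 75)
}

test_that("450-degree extension copies the first quadrant verbatim", {
  s <- mk_sino(360, 20, 1)
  e <- extend_to_450(s)
  expect_equal(nrow(e$values), 450)
  expect_identical(e$values[361:450, ], s$values[1:90, ])
  expect_identical(e$values[361, ], s$values[1, ])

  s5 <- mk_sino(72, 20, 5)
  e5 <- extend_to_450(s5)
  expect_equal(nrow(e5$values), 90)

  expect_error(extend_to_450(e), "360")
  expect_error(extend_to_450(mk_sino(100, 20, 1)), "360")
})

test_that("the LA mask zeroes exactly the 90-360 band and keeps the rest bit-exact", {
  e <- extend_to_450(mk_sino(360, 16, 1))
  la <- apply_la_mask(e)
  expect_equal(sum(!la$mask), 270)
  expect_equal(sum(la$mask), 180)
  expect_true(all(la$sinogram$values[!la$mask, ] == 0))
  expect_identical(la$sinogram$values[la$mask, ], e$values[la$mask, ])
  expect_lte(sum(la$sinogram$values^2), sum(e$values^2))
  # masked rows are the angles in [90, 360)
  ang <- sinogram_angles(e)
  expect_equal(which(!la$mask), which(ang >= 90 & ang < 360))
  expect_error(apply_la_mask(mk_sino(360, 16, 1)), "450")
})

test_that("CE resizing rescales metadata as the dimension ratio", {
  s <- sinogram(matrix(runif(450 * 541), 450), 1.00, bin_pitch_um = 75)
  r <- resize_for_ce(s, 448, 544)
  expect_equal(dim(r$values), c(448, 544))
  expect_equal(r$bin_pitch_um, 74.586, tolerance = 5e-4)
  expect_equal(r$bin_pitch_um, 75 * 541 / 544, tolerance = 1e-12)
  expect_equal(r$angle_step_deg, 1.004, tolerance = 5e-4)
  expect_equal(r$angle_step_deg, 450 / 448, tolerance = 1e-12)

  # a constant sinogram is preserved exactly (bilinear partition of unity)
  cs <- sinogram(matrix(3.25, 180, 176), 2.5, bin_pitch_um = 75)
  rc <- resize_for_ce(cs, 112, 176)
  expect_true(all(abs(rc$values - 3.25) < 1e-12))

  expect_error(resize_for_ce(s, 450, 544), "divisible by 16")
  expect_error(resize_for_ce(mk_sino(100, 20, 1), 448, 544), "within 2x")
})

test_that("fold-back inverts the extension and averages the duplicated band", {
  s <- mk_sino(360, 12, 1)
  e <- extend_to_450(s)
  f <- fold_back_360(e)
  expect_equal(nrow(f$values), 360)
  expect_equal(f$values, s$values, tolerance = 1e-15)

  # a perturbed duplicate band folds to the mean
  e2 <- e
  eps <- 0.3
  e2$values[361:450, ] <- e2$values[361:450, ] + 2 * eps
  f2 <- fold_back_360(e2)
  expect_equal(f2$values[1:90, ], s$values[1:90, ] + eps, tolerance = 1e-12)
  # keep-first leaves the original band untouched
  f3 <- fold_back_360(e2, fold = "keep-first")
  expect_identical(f3$values, s$values)

  expect_error(fold_back_360(s), "450")
})

test_that("fan-beam 450-degree extension is consistent with the projector", {
  geom <- fix_geom(32)
  vox <- fix_grid(geom, 24)
  disc <- fix_disc(24, vox, radius_px = 7)
  sm <- build_system_matrix(geom, 24, seq(0, 355, by = 5), voxel_mm = vox)
  s360 <- forward_project(disc, sm)
  ext <- extend_to_450(s360)
  # rows at theta and theta + 360 from the projector itself agree with the copy
  sm2 <- build_system_matrix(geom, 24, seq(360, 445, by = 5), voxel_mm = vox,
                             cache = FALSE)
  p2 <- forward_project(disc, sm2)
  expect_lt(max(abs(ext$values[73:90, ] - p2$values)), 1e-12)
})

test_that("sinogram files round-trip bit-exactly with metadata checks", {
  s <- mk_sino(45, 20, 2)
  s$known <- rep(c(TRUE, FALSE), length.out = 45)
  path <- tempfile(fileext = ".sino.rds")
  write_sinogram(s, path)
  r <- read_sinogram(path)
  expect_identical(r$values, s$values)
  expect_identical(r$known, s$known)
  expect_equal(r$angle_step_deg, 2)

  # a stack of slices round-trips as written
  stack <- replicate(12, mk_sino(45, 20, 2, seed = sample(1e4, 1)),
                     simplify = FALSE)
  write_sinogram(stack, path)
  r2 <- read_sinogram(path)
  expect_length(r2, 12)
  expect_identical(r2[[7]]$values, stack[[7]]$values)

  # files without sinogram metadata are rejected
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(read_sinogram(bad), "format error|metadata")
  expect_error(write_sinogram(list(1, 2), path), "sinogram")
})

test_that("coverage bookkeeping never drifts through the chain", {
  s <- mk_sino(144, 24, 2.5)
  e <- extend_to_450(s)
  expect_equal(coverage_deg(e), 450)
  la <- apply_la_mask(e)$sinogram
  expect_equal(coverage_deg(la), 450)
  r <- resize_for_ce(la, 112, 16)
  expect_equal(coverage_deg(r), 450, tolerance = 1e-9)
  f <- fold_back_360(la)
  expect_equal(coverage_deg(f), 360)
})
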