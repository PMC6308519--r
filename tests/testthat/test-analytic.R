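test_that("ramp filtering kills DC, is linear, and returns the discrete kernel", {
  h <- 0.069
  set.seed(12)
  # zero DC gain: circular filtering maps constant rows to numerical zero
  cs <- sinogram(matrix(4.2, 8, 64), 1, bin_pitch_um = h * 1000)
  out_c <- ramp_filter_rows(cs, circular = TRUE)
  expect_lt(max(abs(out_c$values)), 1e-10 * 4.2)
  # padded linear convolution confines the constant-row response to the row
  # edges; away from them it is far below the impulse peak 1/(4 h^2)
  out <- ramp_filter_rows(cs)
  expect_lt(max(abs(out$values[, 24:40])), 0.02 * 4.2 / (4 * h^2))

  # linearity
  a <- sinogram(matrix(runif(8 * 64), 8), 1, bin_pitch_um = h * 1000)
  b <- sinogram(matrix(runif(8 * 64), 8), 1, bin_pitch_um = h * 1000)
  ab <- sinogram(a$values + b$values, 1, bin_pitch_um = h * 1000)
  expect_equal(ramp_filter_rows(ab)$values,
               ramp_filter_rows(a)$values + ramp_filter_rows(b)$values,
               tolerance = 1e-12)

  # impulse response: 0-lag 1/(4 h^2), odd lags -1/(pi n h)^2, even lags 0
  imp <- matrix(0, 1, 64); imp[1, 32] <- 1
  fi <- ramp_filter_rows(sinogram(imp, 1, bin_pitch_um = h * 1000))$values[1, ]
  expect_equal(fi[32], 1 / (4 * h^2), tolerance = 1e-3)
  expect_equal(fi[33], -1 / (pi * 1 * h)^2, tolerance = 1e-3)
  expect_equal(fi[31], -1 / (pi * 1 * h)^2, tolerance = 1e-3)
  expect_equal(fi[35], -1 / (pi * 3 * h)^2, tolerance = 2e-2)
  expect_lt(abs(fi[34]), abs(fi[33]) * 1e-2)  # even lag ~ 0
})

test_that("filter specs validate and windows attenuate high frequencies", {
  expect_error(filter_spec(cutoff = 0), "cutoff")
  expect_error(filter_spec(cutoff = 1.5), "cutoff")
  h <- 0.1
  imp <- sinogram({m <- matrix(0, 1, 64); m[1, 32] <- 1; m}, 1,
                  bin_pitch_um = h * 1000)
  ram <- ramp_filter_rows(imp, filter_spec("ramlak"))$values
  han <- ramp_filter_rows(imp, filter_spec("hann"))$values
  expect_lt(max(abs(han)), max(abs(ram)))  # apodisation lowers the peak
})

test_that("FBP reconstructs a disc at the right attenuation scale in both beams", {
  for (beam in c("parallel", "fan_flat")) {
    geom <- fix_geom(96, beam = beam)
    vox <- fix_grid(geom, 64, fill = 0.7)
    disc <- fix_disc(64, vox, radius_px = 14, mu = 0.03)
    sm <- build_system_matrix(geom, 64, projection_angles(protocol_dsfc()),
                              voxel_mm = vox)
    rec <- fbp_reconstruct(forward_project(disc, sm), geom, 64, voxel_mm = vox)
    inner <- unclass(rec)[unclass(disc) > 0 &
                            outer((seq_len(64) - 32.5)^2, (seq_len(64) - 32.5)^2,
                                  `+`) <= 10^2]
    expect_equal(mean(inner), 0.03, tolerance = 0.02)
    expect_gte(psnr(rec, disc), 27)
  }
  # zero sinogram reconstructs to a zero image
  geom <- fix_geom(48)
  z <- sinogram(matrix(0, 10, 48), 36, bin_pitch_um = 75)
  rz <- fbp_reconstruct(z, geom, 32)
  expect_equal(sum(abs(rz)), 0)
})

test_that("angular coverage ordering: more views give higher fidelity; LA is worst", {
  geom <- fix_geom(96)
  vox <- fix_grid(geom, 64, fill = 0.7)
  disc <- fix_disc(64, vox, radius_px = 14, mu = 0.03)
  psnr_at <- function(angles) {
    sm <- build_system_matrix(geom, 64, angles, voxel_mm = vox)
    psnr(fbp_reconstruct(forward_project(disc, sm), geom, 64, voxel_mm = vox),
         disc)
  }
  p256 <- psnr_at(seq(0, 360, length.out = 257)[-257])
  p64 <- psnr_at(seq(0, 360, length.out = 65)[-65])
  p16 <- psnr_at(seq(0, 360, length.out = 17)[-17])
  p_la <- psnr_at(0:89)
  expect_gt(p256, p64)
  expect_gt(p64, p16)
  expect_gt(p256, p_la)
  expect_lt(p_la, p64)
})

test_that("reconstruction is equivariant to rotating the phantom by the angular step", {
  geom <- fix_geom(96, beam = "parallel")
  vox <- fix_grid(geom, 64, fill = 0.7)
  set.seed(13)
  ph <- random_cylinder_phantom(64, cylinder_config(n_cyl_range = c(2, 2),
                                                    radius_range_px = c(6, 9)),
                                voxel_mm = vox, seed = 99)
  # confine support to the inscribed circle so rotation conserves content
  circ <- outer((seq_len(64) - 32.5)^2, (seq_len(64) - 32.5)^2, `+`) <= 26^2
  ph <- slice_image(matrix(as.numeric(ph), 64) * circ, vox)
  angles <- seq(0, 355, by = 5)
  sm <- build_system_matrix(geom, 64, angles, voxel_mm = vox)
  rec1 <- fbp_reconstruct(forward_project(ph, sm), geom, 64, voxel_mm = vox)
  # rotate the phantom by one step and shift sinogram rows by one
  ph_rot <- rotate_image(ph, 5)
  p2 <- forward_project(ph_rot, sm)
  p2_shift <- sinogram(p2$values[c(2:72, 1), ], 5, bin_pitch_um = p2$bin_pitch_um)
  rec2 <- fbp_reconstruct(p2_shift, geom, 64, voxel_mm = vox)
  diff <- abs(unclass(rec2) - unclass(rec1))
  expect_lt(mean(diff), 0.02 * max(rec1))
})
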