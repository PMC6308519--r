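# shared small fixtures, built in code

# paper-style flat-panel geometry with a reduced detector row
fix_geom <- function(det_count = 96, beam = "fan_flat") {
  scan_geometry(299, 325, 75, det_count, beam = beam)
}

# grid/voxel matched to the geometry so the square sits inside the fan FOV
fix_grid <- function(geom, grid_n, fill = 0.7) {
  isocenter_voxel_size(geom) / 1000 * geom$det_count / grid_n * fill
}

# centred uniform disc phantom (radius in pixels)
fix_disc <- function(grid_n, voxel_mm, radius_px = grid_n / 5, mu = 0.03) {
  g <- seq_len(grid_n) - (grid_n + 1) / 2
  img <- matrix(0, grid_n, grid_n)
  img[outer(g^2, g^2, `+`) <= radius_px^2] <- mu
  slice_image(img, voxel_mm)
}

rmse_of <- function(a, b) sqrt(mean((as.numeric(a) - as.numeric(b))^2))

# small cached dataset + architecture for CE unit tests
fix_ce_arch <- function() ce_architecture(64, 32, region_angles = 16)
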