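test_that("architecture shape algebra matches the printed full-scale profile", {
  a <- ce_architecture(544, 448)
  expect_equal(a$bottleneck_hw, c(34L, 28L))
  expect_equal(a$seed_hw, c(34L, 17L))
  expect_equal(a$region_angles, 272L)
  expect_equal(a$seed_hw * 16L, c(544L, 272L))   # seed upsamples onto the region

  d <- ce_architecture(176, 112)
  expect_equal(d$bottleneck_hw, c(11L, 7L))
  expect_equal(d$seed_hw, c(11L, 4L))
  expect_equal(d$region_angles, 64L)
  # region window is centred on the missing band
  expect_equal(range(d$region_cols), c(25L, 88L))

  expect_error(ce_architecture(100, 112), "indivisible")
  expect_error(ce_architecture(176, 112, region_angles = 24), "indivisible")
})

test_that("normalisation maps the data range onto the tanh range and back", {
  expect_equal(ce_normalize(0, c(0, 80)), -1)
  expect_equal(ce_normalize(80, c(0, 80)), 1)
  expect_equal(ce_normalize(40, c(0, 80)), 0)
  set.seed(15)
  x <- matrix(runif(64, 0, 80), 8)
  expect_equal(ce_denormalize(ce_normalize(x, c(0, 80)), c(0, 80)), x,
               tolerance = 1e-6)
  s <- sinogram(x, 1)
  s2 <- ce_denormalize(ce_normalize(s, c(0, 80)), c(0, 80))
  expect_equal(s2$values, x, tolerance = 1e-12)
  expect_error(ce_normalize(x, c(5, 5)), "range collapse")
})

test_that("generator and discriminator respect their output contracts", {
  arch <- ce_architecture(176, 112)
  gen <- build_generator(arch, seed = 21)
  set.seed(22)
  x <- array(runif(176 * 112 * 2, -1, 1), c(176, 112, 1, 2))
  y <- lair:::generator_predict(gen, x)
  expect_equal(dim(y), c(176, 64, 1, 2))
  expect_true(all(y > -1 & y < 1))            # tanh range

  disc <- build_discriminator(arch, seed = 23)
  p1 <- discriminate(disc, y[, , , 1, drop = FALSE])
  expect_gt(p1, 0); expect_lt(p1, 1)
  # inference is deterministic for fixed weights and input
  expect_identical(discriminate(disc, y), discriminate(disc, y))
  # the full-scale region dims are accepted too
  disc544 <- build_discriminator(ce_architecture(544, 448), seed = 24)
  r544 <- array(runif(544 * 272, -1, 1), c(544, 272, 1, 1))
  expect_length(discriminate(disc544, r544), 1)
})

test_that("layer gradients agree with numeric differentiation through the whole generator", {
  arch <- fix_ce_arch()
  gen <- build_generator(arch, seed = 31)
  set.seed(32)
  x <- array(runif(64 * 32 * 2, -1, 1), c(64, 32, 1, 2))
  tr <- array(runif(64 * 16 * 2, -1, 1), c(64, 16, 1, 2))
  lossf <- function() {
    p <- lair:::net_forward(gen$layers, x, training = FALSE)
    mean((p - tr)^2)
  }
  p <- lair:::net_forward(gen$layers, x, training = FALSE)
  lair:::net_backward(gen$layers, 2 * (p - tr) / length(p))
  h <- 1e-6
  for (li in seq_along(gen$layers)) {
    l <- gen$layers[[li]]
    if (!length(l$params)) next
    nm <- names(l$params)[1]
    w0 <- l$params[[nm]][1]
    an <- l$grads[[nm]][1]
    l$params[[nm]][1] <- w0 + h; f1 <- lossf()
    l$params[[nm]][1] <- w0 - h; f2 <- lossf()
    l$params[[nm]][1] <- w0
    expect_equal(an, (f1 - f2) / (2 * h), tolerance = 1e-4,
                 label = sprintf("layer %d (%s) grad[%s]", li, l$type, nm))
  }
})

test_that("masked L2 loss matches an explicit loop oracle", {
  set.seed(41)
  a <- array(runif(5 * 4), c(5, 4)); b <- array(runif(5 * 4), c(5, 4))
  expect_equal(masked_l2_loss(a, a), 0)
  expect_equal(masked_l2_loss(3, 5), 4)        # single element, diff 2
  m <- matrix(runif(20) < 0.5, 5)
  if (!any(m)) m[1, 1] <- TRUE
  acc <- 0; n <- 0
  for (i in 1:5) for (j in 1:4) if (m[i, j]) { acc <- acc + (a[i, j] - b[i, j])^2; n <- n + 1 }
  expect_equal(masked_l2_loss(a, b, m), acc / n, tolerance = 1e-12)
  expect_error(masked_l2_loss(a, b, matrix(FALSE, 5, 4)), "empty mask")
})

test_that("adversarial BCE has its closed-form values and symmetry", {
  expect_equal(adversarial_loss(0.5, "real"), log(2), tolerance = 1e-12)
  expect_equal(adversarial_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(adversarial_loss(0.9999, "real"), 1e-3)
  set.seed(42)
  x <- runif(20, 0.01, 0.99)
  expect_equal(adversarial_loss(x, 1), adversarial_loss(1 - x, 0), tolerance = 1e-12)
})

test_that("a short training run is deterministic, logged, and leaves known rows intact", {
  arch <- fix_ce_arch()
  ds <- generate_dataset(10, "cylinders", grid_n = 48, det_count = 64,
                         step_deg = 11.25, arch = arch, seed = 77)
  cfg <- ce_training_config(epochs = 2, batch_size = 4, val_size = 2,
                            adv_every = 1, disc_batch = 2, seed = 5)
  m1 <- train_ce(ds, arch, cfg)
  m2 <- train_ce(ds, arch, cfg)
  expect_equal(nrow(m1$history), 2)
  expect_equal(m1$history$g_l2[1], m2$history$g_l2[1])  # same seed, same loss
  expect_true(all(is.finite(m1$history$g_l2)))
  expect_true(is.finite(m1$history$d_loss[1]))          # adversarial epoch ran

  # inpainting composites: known rows copied bit-exactly, output flagged
  s <- ds$samples[[1]]$masked
  comp <- inpaint(s, m1)
  expect_true(comp$completed)
  expect_identical(comp$values[s$known, ], s$values[s$known, ])
  expect_true(all(is.finite(comp$values)))
  # inpainted rows lie within the denormalisation range
  expect_gte(min(comp$values[arch$region_cols, ]), m1$range[1] - 1e-9)
  expect_lte(max(comp$values[arch$region_cols, ]), m1$range[2] + 1e-9)
})

test_that("models survive a save/load round trip with identical inference", {
  arch <- fix_ce_arch()
  ds <- generate_dataset(8, "cylinders", grid_n = 48, det_count = 64,
                         step_deg = 11.25, arch = arch, seed = 78)
  m <- train_ce(ds, arch, ce_training_config(epochs = 1, batch_size = 4,
                                             val_size = 2, seed = 9))
  path <- tempfile(fileext = ".ce.rds")
  ce_save_model(m, path)
  m2 <- ce_load_model(path)
  s <- ds$samples[[2]]$masked
  expect_equal(inpaint(s, m2)$values, inpaint(s, m)$values, tolerance = 1e-12)
  expect_error(ce_load_model({p <- tempfile(); saveRDS(1, p); p}), "model")
})

test_that("dataset generation is reproducible and masks agree with values", {
  arch <- ce_architecture(176, 112)
  d1 <- generate_dataset(3, "cylinders", arch = arch, seed = 123)
  d2 <- generate_dataset(3, "cylinders", arch = arch, seed = 123)
  expect_identical(d1$samples[[2]]$complete$values, d2$samples[[2]]$complete$values)
  expect_identical(d1$samples[[3]]$masked$values, d2$samples[[3]]$masked$values)
  s <- d1$samples[[1]]
  expect_equal(dim(s$complete$values), c(112L, 176L))
  # masked equals complete wherever the mask says known
  expect_equal(s$masked$values[s$mask, ], s$complete$values[s$mask, ],
               tolerance = 1e-12)
  # all three phantom families produce valid samples
  for (kind in c("shepp_logan", "digit_like")) {
    dk <- generate_dataset(2, kind, grid_n = 48, det_count = 64,
                           step_deg = 11.25, arch = fix_ce_arch(), seed = 5)
    expect_true(all(is.finite(dk$samples[[1]]$complete$values)))
    expect_gt(max(dk$samples[[1]]$complete$values), 0)
  }
})
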