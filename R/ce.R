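#' Context-encoder architecture specification
#'
#' The generator consumes the full masked sinogram as an image of
#' `bins x angles` (both divisible by 16), encodes it through four stride-2
#' 3x3 convolution stages of depths 2/4/8/16 (LeakyReLU 0.2, batch-norm
#' momentum 0.8, dropout 0.5 on the last stage), passes a channel-wise
#' fully-connected bottleneck from the encoder's `bins/16 x angles/16`
#' feature maps to a `bins/16 x region_angles/16` decoder seed of depth 16,
#' and decodes through four 2x-upsampling 3x3 stages of depths 16/8/4/2
#' (ReLU, batch-norm) into a single-channel tanh output covering only the
#' missing-band region. The discriminator applies 3x3 convolutions of depths
#' 64/128/128 (the first two stride-2) to the region, then a fully-connected
#' map to one sigmoid unit.
#'
#' The missing band of a 450-degree acquisition spans angles `[90, 360)`,
#' i.e. 60 percent of the rows; after resampling to `angles` rows this is
#' rounded to the nearest multiple of 16 (272 for the 448-angle profile, 64
#' for the 112-angle desk profile) and centred on the band.
#'
#' @param bins,angles Input sinogram dimensions (radial bins x angle rows),
#'   each divisible by 16.
#' @param region_angles Width of the inpainted region in angle rows;
#'   `NULL` selects the rounded missing-band width described above.
#' @return A `ce_architecture` list with the region column window
#'   (`region_cols`) and derived shape algebra (`bottleneck_hw`, `seed_hw`).
#' @examples
#' a <- ce_architecture(544, 448)
#' a$bottleneck_hw   # 34 28
#' a$seed_hw         # 34 17
#' a$region_angles   # 272
#' @export
ce_architecture <- function(bins = 544, angles = 448, region_angles = NULL) {
  if (bins %% 16 != 0 || angles %% 16 != 0)
    stop("indivisible dims: 'bins' and 'angles' must be divisible by 16",
         call. = FALSE)
  if (is.null(region_angles)) {
    band <- angles * 270 / 450
    region_angles <- as.integer(floor(band / 16 + 0.5) * 16)  # nearest, ties up
    region_angles <- max(16L, min(region_angles, angles))
  }
  if (region_angles %% 16 != 0 || region_angles > angles)
    stop("indivisible dims: 'region_angles' must be a multiple of 16 <= angles",
         call. = FALSE)
  center <- angles * (90 + 360) / 2 / 450
  start <- as.integer(round(center - region_angles / 2))
  start <- max(0L, min(start, angles - region_angles))
  structure(list(bins = as.integer(bins), angles = as.integer(angles),
                 region_angles = as.integer(region_angles),
                 region_cols = start + seq_len(region_angles),
                 bottleneck_hw = c(bins %/% 16L, angles %/% 16L),
                 seed_hw = c(bins %/% 16L, region_angles %/% 16L),
                 enc_depths = c(2L, 4L, 8L, 16L),
                 dec_depths = c(16L, 8L, 4L, 2L),
                 disc_depths = c(64L, 128L, 128L)),
            class = "ce_architecture")
}

print.ce_architecture <- function(x, ...) {
  cat(sprintf("<ce_architecture> input %d x %d, bottleneck %d x %d, seed %d x %d -> region %d x %d\n",
              x$bins, x$angles, x$bottleneck_hw[1], x$bottleneck_hw[2],
              x$seed_hw[1], x$seed_hw[2], x$bins, x$region_angles))
  invisible(x)
}

#' Affine normalisation between sinogram values and the tanh range
#'
#' Maps `range[1] -> -1` and `range[2] -> +1` (the generator's tanh output
#' range) and back; the round trip is exact to floating point.
#'
#' @param s A [sinogram()], matrix or array.
#' @param range Length-2 data range; the working gray-level window of the
#'   sinogram domain (default `c(0, 80)`).
#' @return Object of the same type with rescaled values.
#' @export
ce_normalize <- function(s, range = c(0, 80)) {
  if (diff(range) <= 0) stop("range collapse", call. = FALSE)
  f <- function(v) 2 * (v - range[1]) / (range[2] - range[1]) - 1
  if (inherits(s, "sinogram")) { s$values <- f(s$values); s } else f(s)
}

#' @rdname ce_normalize
#' @export
ce_denormalize <- function(s, range = c(0, 80)) {
  if (diff(range) <= 0) stop("range collapse", call. = FALSE)
  f <- function(v) (v + 1) / 2 * (range[2] - range[1]) + range[1]
  if (inherits(s, "sinogram")) { s$values <- f(s$values); s } else f(s)
}

#' Build the context-encoder generator
#'
#' @param arch A [ce_architecture()].
#' @param seed Optional RNG seed for weight initialisation.
#' @return A `ce_generator` object; printing it reports the per-stage output
#'   shapes and parameter count.
#' @export
build_generator <- function(arch, seed = NULL) {
  stopifnot(inherits(arch, "ce_architecture"))
  with_seed(seed, {
    d <- arch$enc_depths
    layers <- list(
      nn_conv(1, d[1], 2), nn_lrelu(0.2), nn_bn(d[1]),
      nn_conv(d[1], d[2], 2), nn_lrelu(0.2), nn_bn(d[2]),
      nn_conv(d[2], d[3], 2), nn_lrelu(0.2), nn_bn(d[3]),
      nn_conv(d[3], d[4], 2), nn_lrelu(0.2), nn_bn(d[4]), nn_dropout(0.5),
      nn_cwfc(d[4], arch$bottleneck_hw, arch$seed_hw))
    dd <- arch$dec_depths
    layers <- c(layers, list(
      nn_upsample(), nn_conv(d[4], dd[1], 1), nn_lrelu(0), nn_bn(dd[1]),
      nn_upsample(), nn_conv(dd[1], dd[2], 1), nn_lrelu(0), nn_bn(dd[2]),
      nn_upsample(), nn_conv(dd[2], dd[3], 1), nn_lrelu(0), nn_bn(dd[3]),
      nn_upsample(), nn_conv(dd[3], dd[4], 1), nn_lrelu(0), nn_bn(dd[4]),
      nn_conv(dd[4], 1, 1), nn_tanh()))
    structure(list(layers = layers, arch = arch,
                   opt = local({ e <- new.env(); e$t <- 0L; e })),
              class = "ce_generator")
  })
}

#' Build the context-encoder discriminator
#'
#' @inheritParams build_generator
#' @return A `ce_discriminator` object mapping a region image to a scalar
#'   probability in (0, 1).
#' @export
build_discriminator <- function(arch, seed = NULL) {
  stopifnot(inherits(arch, "ce_architecture"))
  with_seed(seed, {
    dd <- arch$disc_depths
    h <- arch$bins %/% 4L; w <- arch$region_angles %/% 4L
    layers <- list(
      nn_conv(1, dd[1], 2), nn_lrelu(0.2), nn_bn(dd[1]),
      nn_conv(dd[1], dd[2], 2), nn_lrelu(0.2), nn_bn(dd[2]),
      nn_conv(dd[2], dd[3], 1), nn_lrelu(0.2), nn_bn(dd[3]),
      nn_fc(h * w * dd[3], 1))
    structure(list(layers = layers, arch = arch,
                   opt = local({ e <- new.env(); e$t <- 0L; e })),
              class = "ce_discriminator")
  })
}

print.ce_generator <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<ce_generator> %d x %d -> region %d x %d, %d parameters\n",
              a$bins, a$angles, a$bins, a$region_angles,
              net_param_count(x$layers)))
  invisible(x)
}

print.ce_discriminator <- function(x, ...) {
  cat(sprintf("<ce_discriminator> region %d x %d -> (0,1), %d parameters\n",
              x$arch$bins, x$arch$region_angles, net_param_count(x$layers)))
  invisible(x)
}

# forward helpers; x is bins x angles x 1 x B
generator_predict <- function(gen, x, training = FALSE) {
  net_forward(gen$layers, x, training)
}
discriminator_logits <- function(disc, region, training = FALSE) {
  net_forward(disc$layers, region, training)
}

#' Discriminator probability for a region batch
#'
#' @param disc A [build_discriminator()] model.
#' @param region Array `bins x region_angles x 1 x B` (or a single matrix).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
discriminate <- function(disc, region) {
  if (is.matrix(region)) region <- array(region, c(dim(region), 1, 1))
  z <- discriminator_logits(disc, region, training = FALSE)
  as.numeric(1 / (1 + exp(-z)))
}

#' Masked L2 reconstruction loss
#'
#' Mean squared difference over the mask-region elements only.
#'
#' @param pred_region,truth_region Equal-shape arrays.
#' @param mask Logical/0-1 array broadcastable to the region (default all).
#' @return Scalar loss.
#' @export
masked_l2_loss <- function(pred_region, truth_region, mask = NULL) {
  if (!identical(dim(pred_region), dim(truth_region)) &&
      length(pred_region) != length(truth_region))
    stop("shape mismatch", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(pred_region))
  m <- as.logical(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  mean((as.numeric(pred_region)[m] - as.numeric(truth_region)[m])^2)
}

#' Binary cross-entropy adversarial loss
#'
#' `-mean(t log p + (1 - t) log(1 - p))` on discriminator probabilities; the
#' generator is trained against "real" labels on its own outputs.
#'
#' @param disc_out Probabilities in (0, 1).
#' @param target `"real"`/1 or `"fake"`/0 (scalar or per-element).
#' @return Scalar loss.
#' @export
adversarial_loss <- function(disc_out, target) {
  t <- if (is.character(target)) as.numeric(match.arg(target, c("fake", "real")) == "real")
       else as.numeric(target)
  p <- pmin(pmax(as.numeric(disc_out), 1e-12), 1 - 1e-12)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}
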