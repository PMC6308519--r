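#' Context-encoder training configuration
#'
#' Each epoch draws `batch_size` training sinograms and `val_size` validation
#' sinograms at random from the pool (per-epoch resampling; set
#' `sample_per_epoch = FALSE` to sweep the full pool conventionally). The
#' adversarial pathway -- one discriminator update plus the adversarial term
#' in the generator gradient -- runs every `adv_every` epochs; 1 couples them
#' every epoch, larger values amortise the discriminator's cost on small
#' CPUs while the L2 term still drives every update.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Sinograms per generator update (default 32).
#' @param val_size Validation sinograms per epoch (default 16).
#' @param lr,beta1 Adam learning rate and first-moment decay. The desk
#'   defaults (2e-3, 0.9) suit the 300-step single-batch regime, where the
#'   generator update is dominated by the L2 regression term; the full-scale
#'   GAN-family convention (2e-4, 0.5) is selectable for long runs.
#' @param adv_every Epoch period of the adversarial pathway.
#' @param disc_batch Regions per class in each discriminator update (a
#'   random half-batch by default).
#' @param normalization `"sample_max"` (default) scales every sinogram by the
#'   maximum of its measured band -- available at inference from the masked
#'   input alone -- before the affine map onto the tanh range, removing
#'   sample-to-sample amplitude diversity from the learning task; `"global"`
#'   uses the dataset value range directly.
#' @param headroom Half-width of the symmetric normalisation range in units
#'   of the per-sample scale; 1.6 places the measured-band maximum at
#'   tanh ~ 0.6, leaving room for missing-band values that exceed it.
#' @param sample_per_epoch Resample the batch each epoch (default TRUE).
#' @param seed RNG seed covering initialisation, sampling and dropout.
#' @return A `ce_training_config` list.
#' @export
ce_training_config <- function(epochs = 300, batch_size = 32, val_size = 16,
                               lr = 2e-3, beta1 = 0.9, adv_every = 10,
                               disc_batch = 16,
                               normalization = c("sample_max", "global"),
                               headroom = 1.6, sample_per_epoch = TRUE,
                               seed = 1) {
  normalization <- match.arg(normalization)
  stopifnot(epochs >= 1, batch_size >= 1, val_size >= 0, adv_every >= 1,
            disc_batch >= 1, headroom > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_size = as.integer(val_size), lr = lr, beta1 = beta1,
                 adv_every = as.integer(adv_every),
                 disc_batch = as.integer(disc_batch),
                 normalization = normalization, headroom = headroom,
                 sample_per_epoch = isTRUE(sample_per_epoch),
                 seed = seed), class = "ce_training_config")
}

#' Loss weighting between reconstruction and adversarial terms
#'
#' @param recon_weight,adv_weight Nonnegative weights of the masked-region L2
#'   and adversarial losses (defaults 0.999 / 0.001).
#' @return A `ce_loss_spec` list.
#' @export
ce_loss_spec <- function(recon_weight = 0.999, adv_weight = 0.001) {
  if (recon_weight < 0 || adv_weight < 0 || recon_weight + adv_weight <= 0)
    stop("loss weights must be nonnegative with positive sum", call. = FALSE)
  structure(list(recon_weight = recon_weight, adv_weight = adv_weight),
            class = "ce_loss_spec")
}

# per-sample amplitude: the maximum over the measured (known) band, which is
# available at inference time from the masked sinogram alone
ce_sample_scale <- function(masked_values) {
  m <- max(masked_values)
  if (m <= 0) 1 else m
}

# stack selected samples of a ce_dataset into normalized network tensors
ce_tensors <- function(dataset, arch, idx, range, normalization = "sample_max") {
  B <- length(idx)
  X <- array(0, c(arch$bins, arch$angles, 1, B))
  TR <- array(0, c(arch$bins, arch$region_angles, 1, B))
  for (k in seq_along(idx)) {
    s <- dataset$samples[[idx[k]]]
    sc <- if (normalization == "sample_max") ce_sample_scale(s$masked$values) else 1
    X[, , 1, k] <- ce_normalize(t(s$masked$values) / sc, range)
    TR[, , 1, k] <- ce_normalize(t(s$complete$values[arch$region_cols, , drop = FALSE]) / sc,
                                 range)
  }
  list(X = X, TR = TR)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the context-encoder GAN on a limited-angle dataset
#'
#' Alternating updates: the generator minimises
#' `recon_weight * masked-region L2 + adv_weight * BCE(D(pred), real)` and
#' the discriminator distinguishes true missing-band regions from generated
#' ones (both optimised with Adam). Per-epoch training losses and validation
#' region PSNR/UIQI/SSIM (on denormalised values) are logged; the whole run
#' is deterministic given the configuration seed.
#'
#' @param dataset A [generate_dataset()] result (or compatible list).
#' @param arch A [ce_architecture()] matching the dataset sinogram dims.
#' @param train_cfg A [ce_training_config()].
#' @param loss A [ce_loss_spec()].
#' @param holdout Integer indices of samples excluded from training (kept for
#'   testing); default none.
#' @param checkpoint_path Optional path stub; the model is saved there (via
#'   [ce_save_model()]) at the end of training.
#' @param verbose Print a progress line every 50 epochs.
#' @return A `ce_model`: list with `generator`, `discriminator`, `history`
#'   (data frame), `arch`, `range`, `config`.
#' @export
train_ce <- function(dataset, arch, train_cfg = ce_training_config(),
                     loss = ce_loss_spec(), holdout = integer(0),
                     checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(arch, "ce_architecture"))
  d1 <- dim(dataset$samples[[1]]$complete$values)
  if (d1[1] != arch$angles || d1[2] != arch$bins)
    stop("dims mismatch: dataset sinograms are ", d1[1], " x ", d1[2],
         " but the architecture expects ", arch$angles, " x ", arch$bins,
         call. = FALSE)
  range <- if (train_cfg$normalization == "sample_max") {
    c(-train_cfg$headroom, train_cfg$headroom)
  } else {
    dataset$value_range
  }
  pool <- setdiff(seq_along(dataset$samples), holdout)
  if (length(pool) < train_cfg$batch_size + train_cfg$val_size)
    stop("training pool smaller than batch_size + val_size", call. = FALSE)
  with_seed(train_cfg$seed, {
    gen <- build_generator(arch)
    disc <- build_discriminator(arch)
    nreg <- arch$bins * arch$region_angles
    hist <- vector("list", train_cfg$epochs)
    fixed_idx <- NULL
    for (ep in seq_len(train_cfg$epochs)) {
      if (train_cfg$sample_per_epoch || is.null(fixed_idx)) {
        idx <- sample(pool, train_cfg$batch_size + train_cfg$val_size)
        fixed_idx <- idx
      } else idx <- fixed_idx
      tr_idx <- idx[seq_len(train_cfg$batch_size)]
      va_idx <- idx[train_cfg$batch_size + seq_len(train_cfg$val_size)]
      tb <- ce_tensors(dataset, arch, tr_idx, range, train_cfg$normalization)
      B <- train_cfg$batch_size
      pred <- net_forward(gen$layers, tb$X, training = TRUE)
      l2 <- mean((pred - tb$TR)^2)
      dpred <- loss$recon_weight * 2 * (pred - tb$TR) / (nreg * B)
      adv_on <- loss$adv_weight > 0 && (ep %% train_cfg$adv_every == 0)
      g_adv <- NA_real_; d_loss <- NA_real_
      if (adv_on) {
        # the batch order is random, so the leading disc_batch elements are a
        # random subsample for the discriminator pass
        nd <- min(train_cfg$disc_batch, B)
        sub <- seq_len(nd)
        both <- array(0, c(arch$bins, arch$region_angles, 1, 2 * nd))
        both[, , , sub] <- tb$TR[, , , sub, drop = FALSE]
        both[, , , nd + sub] <- pred[, , , sub, drop = FALSE]
        targ <- c(rep(1, nd), rep(0, nd))
        z <- net_forward(disc$layers, both, training = TRUE)
        p <- sigmoid(as.numeric(z))
        d_loss <- adversarial_loss(p, targ)
        dz <- matrix((p - targ) / (2 * nd), 1)
        net_backward(disc$layers, dz)
        adam_step(disc$layers, lr = train_cfg$lr, beta1 = train_cfg$beta1,
                  counter_env = disc$opt)
        # generator adversarial gradient: push D(pred) toward "real"
        zg <- net_forward(disc$layers, pred[, , , sub, drop = FALSE],
                          training = TRUE)
        pg <- sigmoid(as.numeric(zg))
        g_adv <- adversarial_loss(pg, 1)
        dzg <- matrix(loss$adv_weight * (pg - 1) / nd, 1)
        dpred[, , , sub] <- dpred[, , , sub, drop = FALSE] +
          net_backward(disc$layers, dzg)
      }
      net_backward(gen$layers, dpred)
      adam_step(gen$layers, lr = train_cfg$lr, beta1 = train_cfg$beta1,
                counter_env = gen$opt)
      # validation on denormalised region values
      vp <- vu <- vs <- NA_real_
      if (length(va_idx)) {
        vb <- ce_tensors(dataset, arch, va_idx, range, train_cfg$normalization)
        pv <- net_forward(gen$layers, vb$X, training = FALSE)
        pv_d <- ce_denormalize(pv, range); tv_d <- ce_denormalize(vb$TR, range)
        per <- vapply(seq_along(va_idx), function(k)
          c(psnr(pv_d[, , 1, k], tv_d[, , 1, k]),
            uiqi(pv_d[, , 1, k], tv_d[, , 1, k]),
            ssim(pv_d[, , 1, k], tv_d[, , 1, k], L = diff(range))),
          numeric(3))
        vp <- mean(per[1, ]); vu <- mean(per[2, ]); vs <- mean(per[3, ])
      }
      if (!is.finite(l2))
        stop("non-finite generator loss at epoch ", ep,
             " (lr too high or degenerate data)", call. = FALSE)
      hist[[ep]] <- data.frame(epoch = ep, g_l2 = l2, g_adv = g_adv,
                               d_loss = d_loss, val_psnr = vp,
                               val_uiqi = vu, val_ssim = vs)
      if (verbose && ep %% 50 == 0)
        message(sprintf("epoch %d: L2 %.5f, val PSNR %.2f dB", ep, l2, vp))
    }
    model <- structure(list(generator = gen, discriminator = disc,
                            history = do.call(rbind, hist), arch = arch,
                            range = range,
                            normalization = train_cfg$normalization,
                            config = train_cfg, loss = loss),
                       class = "ce_model")
    if (!is.null(checkpoint_path)) ce_save_model(model, checkpoint_path)
    model
  })
}

print.ce_model <- function(x, ...) {
  cat(sprintf("<ce_model> %d epochs trained, final val PSNR %.2f dB (region %d x %d)\n",
              nrow(x$history), utils::tail(x$history$val_psnr, 1),
              x$arch$bins, x$arch$region_angles))
  invisible(x)
}

#' Save / load a trained context-encoder model
#'
#' Weights, architecture and normalisation range are serialized; the
#' optimiser state is not (a reloaded model is for inference or fresh
#' fine-tuning).
#'
#' @param model A `ce_model`.
#' @param path Output path (conventional extension `.ce.rds`).
#' @return `ce_load_model` returns the restored `ce_model`.
#' @export
ce_save_model <- function(model, path) {
  strip <- function(net) lapply(net$layers, function(l)
    list(type = l$type, params = l$params,
         rm = if (l$type == "bn") l$rm, rv = if (l$type == "bn") l$rv,
         meta = mget(intersect(c("cin", "cout", "stride", "slope", "rate",
                                 "momentum", "eps", "channels", "in_hw",
                                 "out_hw", "n_in", "n_out"), ls(l)), envir = l)))
  saveRDS(list(format = "lair-ce-model", version = 1L,
               arch = model$arch, range = model$range,
               normalization = model$normalization,
               history = model$history,
               generator = strip(model$generator),
               discriminator = strip(model$discriminator)), path)
  invisible(path)
}

#' @rdname ce_save_model
#' @export
ce_load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "lair-ce-model"))
    stop("not a serialized context-encoder model", call. = FALSE)
  rebuild <- function(stored, builder) {
    net <- builder(obj$arch)
    for (k in seq_along(net$layers)) {
      net$layers[[k]]$params <- stored[[k]]$params
      if (stored[[k]]$type == "bn") {
        net$layers[[k]]$rm <- stored[[k]]$rm
        net$layers[[k]]$rv <- stored[[k]]$rv
      }
    }
    net
  }
  structure(list(generator = rebuild(obj$generator, build_generator),
                 discriminator = rebuild(obj$discriminator, build_discriminator),
                 history = obj$history, arch = obj$arch, range = obj$range,
                 normalization = obj$normalization),
            class = "ce_model")
}

#' Inpaint the missing band of a limited-angle sinogram
#'
#' Runs the trained generator on the normalised masked sinogram and composites
#' the result: known rows are copied bit-exactly from the input; rows of the
#' missing band covered by the generator's region window take the
#' denormalised prediction. The output is flagged `completed`.
#'
#' @param s_la A [sinogram()] whose dimensions match the model architecture
#'   (angle rows x bins), with a `known` row mask.
#' @param model A trained `ce_model` (or list with `generator`, `arch`,
#'   `range`).
#' @return The completed [sinogram()].
#' @export
inpaint <- function(s_la, model) {
  arch <- model$arch
  stopifnot(inherits(s_la, "sinogram"))
  d <- dim(s_la$values)
  if (d[1] != arch$angles || d[2] != arch$bins)
    stop("dims mismatch: sinogram is ", d[1], " x ", d[2],
         " but the model expects ", arch$angles, " x ", arch$bins, call. = FALSE)
  known <- if (!is.null(s_la$known)) s_la$known else rep(FALSE, d[1])
  sc <- if (identical(model$normalization, "sample_max")) ce_sample_scale(s_la$values) else 1
  x <- array(ce_normalize(t(s_la$values) / sc, model$range),
             c(arch$bins, arch$angles, 1, 1))
  pred <- net_forward(model$generator$layers, x, training = FALSE)
  region <- sc * ce_denormalize(pred[, , 1, 1], model$range)  # bins x region_angles
  out <- s_la
  fill_rows <- intersect(arch$region_cols, which(!known))
  out$values[fill_rows, ] <- t(region[, match(fill_rows, arch$region_cols),
                                      drop = FALSE])
  out$known <- known | seq_len(d[1]) %in% arch$region_cols
  out$completed <- TRUE
  out
}
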