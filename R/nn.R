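# Minimal BLAS-backed neural-network engine for the context encoder.
#
# A tensor is a list(m, H, W, B): `m` is a ((H*W*B) x C) matrix whose rows
# are ordered height-fastest, then width, then batch, and whose columns are
# channels. In this layout a 3x3 convolution is nine row-subset GEMMs (one
# per kernel offset) with no transposition, batch norm is column arithmetic,
# and the channel-wise fully-connected bottleneck is a per-column reshape.
# Each layer is an environment holding parameters, Adam state, cached
# row-index tables (keyed by input dims) and the forward cache.

nn_tensor <- function(m, H, W, B) list(m = m, H = H, W = W, B = B)

# array H x W x C x B  <->  tensor
nn_from_array <- function(a) {
  d <- dim(a)
  m <- matrix(aperm(a, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  nn_tensor(m, d[1], d[2], d[4])
}
nn_to_array <- function(t) {
  C <- ncol(t$m)
  aperm(array(t$m, c(t$H, t$W, t$B, C)), c(1, 2, 4, 3))
}

nn_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- list(); e$grads <- list(); e$idx <- list()
  e
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

nn_conv <- function(cin, cout, stride = 1) {
  l <- nn_layer("conv", cin = cin, cout = cout, stride = stride)
  # weight rows ordered offset-within-3x3 (column-major) fastest, then cin
  l$params <- list(W = glorot(9 * cin, cout, c(9 * cin, cout)), b = numeric(cout))
  l
}
nn_bn <- function(c, momentum = 0.8, eps = 1e-5) {
  l <- nn_layer("bn", momentum = momentum, eps = eps,
                rm = numeric(c), rv = rep(1, c))
  l$params <- list(gamma = rep(1, c), beta = numeric(c))
  l
}
nn_lrelu <- function(slope = 0.2) nn_layer("lrelu", slope = slope)
nn_tanh <- function() nn_layer("tanh")
nn_dropout <- function(rate = 0.5) nn_layer("dropout", rate = rate)
nn_upsample <- function() nn_layer("upsample")
nn_cwfc <- function(channels, in_hw, out_hw) {
  n_in <- prod(in_hw); n_out <- prod(out_hw)
  l <- nn_layer("cwfc", channels = channels, in_hw = in_hw, out_hw = out_hw)
  l$params <- list(W = glorot(n_in, n_out, c(n_in, n_out, channels)),
                   b = matrix(0, n_out, channels))
  l
}
nn_fc <- function(n_in, n_out) {
  l <- nn_layer("fc", n_in = n_in, n_out = n_out)
  l$params <- list(W = glorot(n_in, n_out, c(n_in, n_out)), b = numeric(n_out))
  l
}

upsample_tables <- function(l, H, W, B) {
  key <- paste(H, W, B)
  tb <- l$idx[[key]]
  if (!is.null(tb)) return(tb)
  Ho <- 2L * H; Wo <- 2L * W
  src_r <- rep(seq_len(H), each = 2L)
  src_c <- rep(seq_len(W), each = 2L)
  base <- outer(src_r, (src_c - 1L) * H, `+`)          # Ho x Wo source rows
  up <- as.vector(outer(as.vector(base), (seq_len(B) - 1L) * H * W, `+`))
  # backward: the 4 output rows fed by each source cell
  pick <- function(r0, c0) {
    b2 <- outer(seq(r0, Ho, 2L), (seq(c0, Wo, 2L) - 1L) * Ho, `+`)
    as.vector(outer(as.vector(b2), (seq_len(B) - 1L) * Ho * Wo, `+`))
  }
  tb <- list(up = up, g = list(pick(1L, 1L), pick(2L, 1L), pick(1L, 2L), pick(2L, 2L)),
             Ho = Ho, Wo = Wo, H = H, W = W, B = B)
  l$idx[[key]] <- tb
  tb
}

nn_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    conv = {
      l$cache <- x
      Y <- cpp_conv3x3_fwd(x$m, x$H, x$W, x$B, l$params$W, l$params$b, l$stride)
      nn_tensor(Y, ceiling(x$H / l$stride), ceiling(x$W / l$stride), x$B)
    },
    bn = {
      if (training) {
        r <- cpp_bn_fwd(x$m, l$params$gamma, l$params$beta, l$eps)
        l$rm <- l$momentum * l$rm + (1 - l$momentum) * r$mu
        l$rv <- l$momentum * l$rv + (1 - l$momentum) * r$var
        l$cache <- list(xhat = r$xhat, istd = r$istd, training = TRUE)
        nn_tensor(r$y, x$H, x$W, x$B)
      } else {
        istd <- 1 / sqrt(l$rv + l$eps)
        n <- nrow(x$m)
        xhat <- (x$m - rep(l$rm, each = n)) * rep(istd, each = n)
        l$cache <- list(xhat = xhat, istd = istd, training = FALSE)
        y <- xhat * rep(l$params$gamma, each = n) + rep(l$params$beta, each = n)
        nn_tensor(y, x$H, x$W, x$B)
      }
    },
    lrelu = {
      l$cache <- x$m
      nn_tensor(cpp_lrelu_fwd(x$m, l$slope), x$H, x$W, x$B)
    },
    tanh = { y <- tanh(x$m); l$cache <- y; nn_tensor(y, x$H, x$W, x$B) },
    dropout = {
      if (!training) { l$cache <- NULL; x }
      else {
        keep <- 1 - l$rate
        m <- (matrix(stats::runif(length(x$m)), nrow(x$m)) < keep) / keep
        l$cache <- m
        nn_tensor(x$m * m, x$H, x$W, x$B)
      }
    },
    upsample = {
      tb <- upsample_tables(l, x$H, x$W, x$B)
      l$cache <- tb
      nn_tensor(x$m[tb$up, , drop = FALSE], tb$Ho, tb$Wo, x$B)
    },
    cwfc = {
      C <- l$channels
      n_in <- prod(l$in_hw); n_out <- prod(l$out_hw)
      l$cache <- x
      Y <- matrix(0, n_out * x$B, C)
      for (cc in seq_len(C)) {
        Xc <- matrix(x$m[, cc], n_in, x$B)
        Y[, cc] <- crossprod(l$params$W[, , cc], Xc) + l$params$b[, cc]
      }
      nn_tensor(Y, l$out_hw[1], l$out_hw[2], x$B)
    },
    fc = {
      # flatten (spatial, channel) per batch element: S*C x B
      C <- ncol(x$m); S <- x$H * x$W
      X <- matrix(aperm(array(x$m, c(S, x$B, C)), c(1, 3, 2)), S * C, x$B)
      l$cache <- list(X = X, S = S, C = C, B = x$B, H = x$H, W = x$W)
      crossprod(l$params$W, X) + l$params$b    # n_out x B (logits, plain matrix)
    },
    stop("unknown layer type ", l$type))
}

nn_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      x <- l$cache
      g <- cpp_conv3x3_bwd(x$m, dy$m, x$H, x$W, x$B, l$params$W, l$stride)
      l$grads <- list(W = g$dW, b = colSums(dy$m))
      nn_tensor(g$dx, x$H, x$W, x$B)
    },
    bn = {
      ch <- l$cache
      r <- cpp_bn_bwd(dy$m, ch$xhat, l$params$gamma, ch$istd, ch$training)
      l$grads <- list(gamma = r$dgamma, beta = r$dbeta)
      nn_tensor(r$dx, dy$H, dy$W, dy$B)
    },
    lrelu = nn_tensor(cpp_lrelu_bwd(l$cache, dy$m, l$slope), dy$H, dy$W, dy$B),
    tanh = nn_tensor(dy$m * (1 - l$cache^2), dy$H, dy$W, dy$B),
    dropout = if (is.null(l$cache)) dy
              else nn_tensor(dy$m * l$cache, dy$H, dy$W, dy$B),
    upsample = {
      tb <- l$cache
      dx <- dy$m[tb$g[[1]], , drop = FALSE] + dy$m[tb$g[[2]], , drop = FALSE] +
            dy$m[tb$g[[3]], , drop = FALSE] + dy$m[tb$g[[4]], , drop = FALSE]
      nn_tensor(dx, tb$H, tb$W, tb$B)
    },
    cwfc = {
      x <- l$cache; C <- l$channels
      n_in <- prod(l$in_hw); n_out <- prod(l$out_hw)
      dW <- array(0, dim(l$params$W)); db <- matrix(0, n_out, C)
      dx <- matrix(0, n_in * x$B, C)
      for (cc in seq_len(C)) {
        Xc <- matrix(x$m[, cc], n_in, x$B)
        dYc <- matrix(dy$m[, cc], n_out, x$B)
        dW[, , cc] <- tcrossprod(Xc, dYc)
        db[, cc] <- rowSums(dYc)
        dx[, cc] <- l$params$W[, , cc] %*% dYc
      }
      l$grads <- list(W = dW, b = db)
      nn_tensor(dx, l$in_hw[1], l$in_hw[2], x$B)
    },
    fc = {
      ch <- l$cache
      l$grads <- list(W = tcrossprod(ch$X, dy), b = rowSums(dy))
      dX <- l$params$W %*% dy                       # S*C x B
      m <- matrix(aperm(array(dX, c(ch$S, ch$C, ch$B)), c(1, 3, 2)),
                  ch$S * ch$B, ch$C)
      nn_tensor(m, ch$H, ch$W, ch$B)
    },
    stop("unknown layer type ", l$type))
}

net_forward <- function(layers, x, training = TRUE) {
  if (is.array(x) && length(dim(x)) == 4) x <- nn_from_array(x)
  for (l in layers) x <- nn_forward(l, x, training)
  if (is.list(x) && !is.null(x$m)) nn_to_array(x) else x
}
net_backward <- function(layers, dy) {
  n <- length(layers)
  if (is.array(dy) && length(dim(dy)) == 4) dy <- nn_from_array(dy)
  for (l in rev(layers)) dy <- nn_backward(l, dy)
  if (is.list(dy) && !is.null(dy$m)) nn_to_array(dy) else dy
}

adam_step <- function(layers, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      counter_env) {
  counter_env$t <- counter_env$t + 1L
  t <- counter_env$t
  for (l in layers) {
    if (!length(l$params)) next
    if (is.null(l$m)) {
      l$m <- lapply(l$params, function(p) p * 0)
      l$v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$m[[nm]] <- beta1 * l$m[[nm]] + (1 - beta1) * g
      l$v[[nm]] <- beta2 * l$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$m[[nm]] / (1 - beta1^t)
      vhat <- l$v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

net_param_count <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, length, 1L)), 1L))
}
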