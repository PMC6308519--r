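#' Iterative reconstruction configuration
#'
#' Hyperparameters for the two TV-constrained optimizers. `lambda` is the
#' relaxation weight balancing the data-fidelity and TV stages; the ASD
#' parameters follow the usual adaptive-steepest-descent bookkeeping
#' (`beta` SART relaxation decayed by `beta_red` each iteration; TV step
#' `alpha_frac * ||data update||`, shrunk by `alpha_red` whenever the TV
#' descent travels more than `r_max` times the data step).
#'
#' @param algorithm `"em_tv"` or `"asd_pocs"`.
#' @param lambda Relaxation weight (>= 0) of the TV stage.
#' @param tv_steps TV descent sub-steps per iteration.
#' @param tv_step_size Relative TV step length (EM-TV).
#' @param max_iters Iteration budget (>= 1).
#' @param epsilon_tv Smoothing constant of the differentiable TV (> 0).
#' @param beta,beta_red,alpha_frac,alpha_red,r_max ASD-POCS controls.
#' @return An `ir_config` list.
#' @export
ir_config <- function(algorithm = c("em_tv", "asd_pocs"), lambda = 0.2,
                      tv_steps = 10, tv_step_size = 0.1, max_iters = 50,
                      epsilon_tv = 1e-6, beta = 1.0, beta_red = 0.995,
                      alpha_frac = 0.2, alpha_red = 0.95, r_max = 0.95) {
  algorithm <- match.arg(algorithm)
  stopifnot(lambda >= 0, max_iters >= 1, epsilon_tv > 0, tv_steps >= 0)
  structure(list(algorithm = algorithm, lambda = lambda, tv_steps = tv_steps,
                 tv_step_size = tv_step_size, max_iters = as.integer(max_iters),
                 epsilon_tv = epsilon_tv, beta = beta, beta_red = beta_red,
                 alpha_frac = alpha_frac, alpha_red = alpha_red, r_max = r_max),
            class = "ir_config")
}

#' Image-quality stopping rule configuration
#'
#' Iteration stops early once the IQ score `s = UIQI - rTV` (computed against
#' the reference image) has not improved for `patience` iterations among the
#' iterates whose PSNR exceeds the `k_psnr` gate; the returned iterate is the
#' argmax-`s` eligible iterate. `metric = "uiqi_minus_abs_rtv_dev"` swaps in
#' the variant `UIQI - |rTV - 1|` whose rTV term is optimal at 1.
#'
#' @param k_psnr PSNR gate in dB (default the 35 dB working threshold).
#' @param patience Iterations without improvement tolerated (>= 1).
#' @param metric `"uiqi_minus_rtv"` (literal form) or
#'   `"uiqi_minus_abs_rtv_dev"`.
#' @return A `stopping_config` list.
#' @export
stopping_config <- function(k_psnr = 35, patience = 3,
                            metric = c("uiqi_minus_rtv", "uiqi_minus_abs_rtv_dev")) {
  metric <- match.arg(metric)
  stopifnot(patience >= 1)
  structure(list(k_psnr = k_psnr, patience = as.integer(patience),
                 metric = metric), class = "stopping_config")
}

iq_score <- function(uiqi_v, rtv_v, metric) {
  if (metric == "uiqi_minus_rtv") uiqi_v - rtv_v else uiqi_v - abs(rtv_v - 1)
}

#' Decide whether to stop an iterative run on its IQ record
#'
#' Operates on the per-iteration IQ record accumulated so far: among
#' iterations whose PSNR exceeds the gate, it tracks `s = UIQI - rTV` and
#' requests a stop when `s` has not improved for `patience` eligible
#' iterations; the selected iterate is the argmax-`s` eligible one. If no
#' iteration has passed the gate the run continues (and a caller reaching its
#' budget should return the last iterate with reason `"psnr-gate-unmet"`).
#'
#' @param report Data frame with columns `psnr`, `uiqi`, `rtv` (one row per
#'   iteration so far, >= 1 rows).
#' @param stop A [stopping_config()].
#' @return List with `action` (`"continue"`/`"stop"`), `best_iter` (argmax-s
#'   eligible iteration index, `NA` if none eligible) and `reason`.
#' @export
iq_stop_decision <- function(report, stop = stopping_config()) {
  stopifnot(inherits(stop, "stopping_config"), nrow(report) >= 1)
  s <- iq_score(report$uiqi, report$rtv, stop$metric)
  eligible <- which(report$psnr > stop$k_psnr)
  if (!length(eligible))
    return(list(action = "continue", best_iter = NA_integer_,
                reason = "psnr-gate-unmet"))
  best <- eligible[which.max(s[eligible])]
  since <- sum(eligible > best)
  if (since >= stop$patience)
    list(action = "stop", best_iter = best, reason = "iq-plateau")
  else
    list(action = "continue", best_iter = best, reason = "improving")
}

# --- shared iteration harness -------------------------------------------

pvec_of <- function(p, sm) {
  vals <- if (inherits(p, "sinogram")) p$values else p
  if (nrow(vals) != length(sm$angles_deg) || ncol(vals) != sm$geom$det_count)
    stop("shape mismatch between projection data and system matrix", call. = FALSE)
  as.numeric(t(vals))
}

record_iq <- function(f, reference, resid, metric) {
  if (is.null(reference)) {
    data.frame(psnr = NA_real_, uiqi = NA_real_, ssim = NA_real_,
               rtv = NA_real_, data_residual = resid)
  } else {
    r <- as_matrix_any(reference)
    data.frame(psnr = psnr(f, r), uiqi = uiqi(f, r),
               ssim = if (min(dim(f)) >= 11) ssim(f, r) else ssim(f, r, mode = "global"),
               rtv = tv_norm(f) / max(tv_norm(r), .Machine$double.eps),
               data_residual = resid)
  }
}

finish_report <- function(metrics, stop_iteration, reason, cfg, stop) {
  structure(list(metrics = metrics, stop_iteration = stop_iteration,
                 reason = reason, algorithm = cfg$algorithm,
                 config = cfg, stopping = stop),
            class = "iq_report")
}

print.iq_report <- function(x, ...) {
  cat(sprintf("<iq_report> %s: %d iterations recorded, stopped at %s (%s)\n",
              x$algorithm, nrow(x$metrics),
              ifelse(is.na(x$stop_iteration), "budget", x$stop_iteration),
              x$reason))
  invisible(x)
}

#' One multiplicative EM (MLEM) fidelity update
#'
#' `f' = f * A^T(p / (A f)) / (A^T 1)` with the `0/0 := 0` convention.
#' Nonnegativity is preserved; consistent strictly positive data are a fixed
#' point. Rays with `A f = 0` but `p > 0` are inconsistent and flagged via a
#' warning and the `"inconsistent"` attribute.
#'
#' @param f Current image (matrix or [slice_image()]), nonnegative.
#' @param p Projection data ([sinogram()] or matrix).
#' @param sm A [build_system_matrix()] result.
#' @param warn Emit the inconsistency warning (callers looping over updates
#'   warn once).
#' @return Updated image matrix (with `voxel_mm`-less plain storage).
#' @export
em_update <- function(f, p, sm, warn = TRUE) {
  stopifnot(inherits(sm, "system_matrix"))
  fv <- as.vector(as_matrix_any(f))
  pv <- pvec_of(p, sm)
  af <- as.numeric(sm$A %*% fv)
  # rays that never intersect the grid cannot carry signal; only rays with
  # support count as inconsistent
  has_support <- Matrix::rowSums(sm$A != 0) > 0
  bad <- af <= 0 & pv > 0 & has_support
  if (any(bad) && warn) {
    warning("inconsistent data: ", sum(bad), " rays with p > 0 but A f = 0",
            call. = FALSE)
  }
  ratio <- ifelse(af > 0, pv / af, 0)
  sens <- as.numeric(Matrix::crossprod(sm$A, rep(1, length(pv))))
  num <- as.numeric(Matrix::crossprod(sm$A, ratio))
  out <- ifelse(sens > 0, fv * num / sens, 0)
  res <- matrix(out, nrow(f), ncol(f))
  attr(res, "inconsistent") <- any(bad)
  res
}

#' EM-TV reconstruction with the IQ stopping rule
#'
#' Alternates the multiplicative EM fidelity update with `tv_steps` descent
#' steps on the smoothed TV, each of length
#' `lambda * tv_step_size * ||EM update|| / tv_steps` along the unit TV
#' gradient; negatives are clamped to zero after the TV stage. Per-iteration
#' PSNR/UIQI/SSIM/rTV against `reference` and the data residual are recorded;
#' with a [stopping_config()] and a reference the argmax-score iterate is
#' returned, otherwise the final one.
#'
#' @param p Projection data ([sinogram()] or matrix).
#' @param sm A [build_system_matrix()] result.
#' @param cfg An [ir_config()].
#' @param stop A [stopping_config()] or `NULL` to run the full budget.
#' @param reference Reference image for the IQ metrics (ground-truth phantom
#'   in simulation; the FBP of the completed sinogram otherwise); `NULL`
#'   disables IQ recording.
#' @return List with `image` ([slice_image()]) and `report` (`iq_report`).
#' @export
em_tv_reconstruct <- function(p, sm, cfg = ir_config("em_tv"), stop = NULL,
                              reference = NULL) {
  pv <- pvec_of(p, sm)
  n <- sm$grid_n
  # uniform positive start matched in total mass: sum(A f0) = sum(p)
  tot_a <- sum(sm$A@x)
  f0_val <- if (sum(pv) > 0 && tot_a > 0) sum(pv) / tot_a else 1
  f <- matrix(max(f0_val, 1e-12), n, n)
  metrics <- NULL
  best <- list(iter = NA_integer_, s = -Inf, f = NULL)
  up_count <- 0L; prev_res <- Inf
  reason <- "max-iters"; stop_iter <- NA_integer_
  last_f <- f
  for (it in seq_len(cfg$max_iters)) {
    f_em <- em_update(f, p, sm, warn = (it == 1L))
    delta_em <- sqrt(sum((f_em - f)^2))
    f <- f_em
    if (cfg$lambda > 0 && cfg$tv_steps > 0 && delta_em > 0) {
      step <- cfg$lambda * cfg$tv_step_size * delta_em / cfg$tv_steps
      for (k in seq_len(cfg$tv_steps)) {
        g <- tv_gradient(f, cfg$epsilon_tv)
        gn <- sqrt(sum(g^2))
        if (gn == 0) break
        f <- f - step * (g / gn)
      }
      f[f < 0] <- 0
    }
    resid <- sqrt(sum((as.numeric(sm$A %*% as.vector(f)) - pv)^2))
    row <- record_iq(f, reference, resid, if (!is.null(stop)) stop$metric else "uiqi_minus_rtv")
    metrics <- rbind(metrics, row)
    last_f <- f
    if (!is.null(reference)) {
      s <- iq_score(row$uiqi, row$rtv, if (!is.null(stop)) stop$metric else "uiqi_minus_rtv")
      gate_ok <- is.null(stop) || row$psnr > stop$k_psnr
      if (gate_ok && s > best$s) best <- list(iter = it, s = s, f = f)
    }
    if (resid == 0) { reason <- "exact-fit"; stop_iter <- it; break }
    up_count <- if (resid > prev_res) up_count + 1L else 0L
    prev_res <- resid
    if (up_count >= 5L) { reason <- "diverged"; stop_iter <- it; break }
    if (!is.null(stop) && !is.null(reference)) {
      dec <- iq_stop_decision(metrics, stop)
      if (dec$action == "stop") { reason <- dec$reason; stop_iter <- it; break }
    }
  }
  sel <- if (!is.null(stop) && !is.null(reference) && !is.null(best$f)) {
    stop_sel <- best$iter
    best$f
  } else {
    if (!is.null(stop) && !is.null(reference) && is.null(best$f))
      reason <- "psnr-gate-unmet"
    stop_sel <- if (is.na(stop_iter)) nrow(metrics) else stop_iter
    last_f
  }
  report <- finish_report(metrics, stop_sel, reason, cfg, stop)
  report$selected_iteration <- stop_sel
  list(image = slice_image(sel, sm$voxel_mm), report = report)
}

#' ASD-POCS reconstruction with the IQ stopping rule
#'
#' Per iteration: a view-sequential SART fidelity pass -- for each projection
#' view `v` in turn, `f += beta * A_v^T((p_v - A_v f) / A_v 1) / A_v^T 1`
#' with nonnegativity projection -- then
#' an adaptive TV descent of `tv_steps` unit-gradient steps with total length
#' `alpha_frac * ||data update||`; `alpha_frac` shrinks by `alpha_red`
#' whenever the TV travel exceeds `r_max` times the data travel, and `beta`
#' decays by `beta_red` each iteration.
#'
#' @inheritParams em_tv_reconstruct
#' @param cfg An [ir_config()] (fields `beta`, `beta_red`, `alpha_frac`,
#'   `alpha_red`, `r_max`).
#' @return List with `image` ([slice_image()]) and `report` (`iq_report`);
#'   the report carries the realised `beta_sequence`.
#' @export
asd_pocs_reconstruct <- function(p, sm, cfg = ir_config("asd_pocs"), stop = NULL,
                                 reference = NULL) {
  pv <- pvec_of(p, sm)
  n <- sm$grid_n
  n_det <- sm$geom$det_count
  n_views <- length(sm$angles_deg)
  # view-sequential SART blocks: per-view operator, chord lengths A_v 1 and
  # sensitivities A_v^T 1
  views <- lapply(seq_len(n_views), function(v) {
    rows <- (v - 1L) * n_det + seq_len(n_det)
    Av <- sm$A[rows, , drop = FALSE]
    ray_len <- as.numeric(Av %*% rep(1, n * n))
    sens <- as.numeric(Matrix::colSums(Av))
    list(Av = Av, p = pv[rows], inv_len = ifelse(ray_len > 0, 1 / ray_len, 0),
         inv_sens = ifelse(sens > 0, 1 / sens, 0))
  })
  f <- matrix(0, n, n)
  beta <- cfg$beta; alpha_frac <- cfg$alpha_frac
  beta_seq <- numeric(0)
  metrics <- NULL
  best <- list(iter = NA_integer_, s = -Inf, f = NULL)
  up_count <- 0L; prev_res <- Inf
  reason <- "max-iters"; stop_iter <- NA_integer_
  last_f <- f
  for (it in seq_len(cfg$max_iters)) {
    f0 <- f
    fv <- as.vector(f)
    for (v in views) {
      r <- (v$p - as.numeric(v$Av %*% fv)) * v$inv_len
      fv <- fv + beta * as.numeric(Matrix::crossprod(v$Av, r)) * v$inv_sens
      fv[fv < 0] <- 0
    }
    f <- matrix(fv, n, n)
    dp <- sqrt(sum((f - f0)^2))
    f_pocs <- f
    if (cfg$tv_steps > 0 && dp > 0) {
      alpha <- alpha_frac * dp / cfg$tv_steps
      for (k in seq_len(cfg$tv_steps)) {
        g <- tv_gradient(f, cfg$epsilon_tv)
        gn <- sqrt(sum(g^2))
        if (gn == 0) break
        f <- f - alpha * (g / gn)
      }
      f[f < 0] <- 0
      dtv <- sqrt(sum((f - f_pocs)^2))
      if (dtv > cfg$r_max * dp) alpha_frac <- alpha_frac * cfg$alpha_red
    }
    beta_seq <- c(beta_seq, beta)
    beta <- beta * cfg$beta_red
    resid <- sqrt(sum((as.numeric(sm$A %*% as.vector(f)) - pv)^2))
    row <- record_iq(f, reference, resid, if (!is.null(stop)) stop$metric else "uiqi_minus_rtv")
    metrics <- rbind(metrics, row)
    last_f <- f
    if (!is.null(reference)) {
      s <- iq_score(row$uiqi, row$rtv, if (!is.null(stop)) stop$metric else "uiqi_minus_rtv")
      gate_ok <- is.null(stop) || row$psnr > stop$k_psnr
      if (gate_ok && s > best$s) best <- list(iter = it, s = s, f = f)
    }
    if (resid == 0) { reason <- "exact-fit"; stop_iter <- it; break }
    up_count <- if (resid > prev_res) up_count + 1L else 0L
    prev_res <- resid
    if (up_count >= 5L) { reason <- "diverged"; stop_iter <- it; break }
    if (!is.null(stop) && !is.null(reference)) {
      dec <- iq_stop_decision(metrics, stop)
      if (dec$action == "stop") { reason <- dec$reason; stop_iter <- it; break }
    }
  }
  sel <- if (!is.null(stop) && !is.null(reference) && !is.null(best$f)) {
    stop_sel <- best$iter
    best$f
  } else {
    if (!is.null(stop) && !is.null(reference) && is.null(best$f))
      reason <- "psnr-gate-unmet"
    stop_sel <- if (is.na(stop_iter)) nrow(metrics) else stop_iter
    last_f
  }
  report <- finish_report(metrics, stop_sel, reason, cfg, stop)
  report$selected_iteration <- stop_sel
  report$beta_sequence <- beta_seq
  list(image = slice_image(sel, sm$voxel_mm), report = report)
}
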