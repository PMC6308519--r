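#' Sinogram container
#'
#' Angle-major matrix of line integrals (dimensionless, attenuation x length):
#' row `a` holds the projection at angle `angle_start + (a-1) * angle_step_deg`
#' across `n_det` detector bins. An optional per-angle logical `known` mask
#' distinguishes measured rows from missing (zero-filled) ones.
#'
#' @param values `n_angles x n_det` numeric matrix.
#' @param angle_step_deg Angular step between rows (degrees).
#' @param angle_start First row angle (degrees), default 0.
#' @param bin_pitch_um Radial (detector bin) sampling in micrometres.
#' @param known Optional logical vector, one entry per angle row.
#' @param completed Logical flag set by the inpainting step.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, angle_step_deg, angle_start = 0,
                     bin_pitch_um = NA_real_, known = NULL, completed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("sinogram values must be finite", call. = FALSE)
  if (!is.numeric(angle_step_deg) || angle_step_deg <= 0)
    stop("'angle_step_deg' must be positive", call. = FALSE)
  if (!is.null(known)) {
    known <- as.logical(known)
    if (length(known) != nrow(values))
      stop("'known' mask length must equal the number of angle rows", call. = FALSE)
  }
  structure(list(values = values, angle_step_deg = as.numeric(angle_step_deg),
                 angle_start = as.numeric(angle_start),
                 bin_pitch_um = as.numeric(bin_pitch_um),
                 known = known, completed = isTRUE(completed)),
            class = "sinogram")
}

#' @rdname sinogram
#' @param s A `sinogram`.
#' @export
coverage_deg <- function(s) {
  stopifnot(inherits(s, "sinogram"))
  nrow(s$values) * s$angle_step_deg
}

#' @rdname sinogram
#' @export
sinogram_angles <- function(s) {
  stopifnot(inherits(s, "sinogram"))
  s$angle_start + (seq_len(nrow(s$values)) - 1) * s$angle_step_deg
}

print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, step %g deg (coverage %g deg)%s%s\n",
              nrow(x$values), ncol(x$values), x$angle_step_deg, coverage_deg(x),
              if (!is.null(x$known)) sprintf(", %d known rows", sum(x$known)) else "",
              if (x$completed) ", completed" else ""))
  invisible(x)
}

#' Extend a 360-degree sinogram to 450 degrees
#'
#' A full-rotation sinogram repeats after 360 degrees, so the first 90 degrees
#' of rows are copied verbatim after the 360-degree mark. The result is the
#' reference sinogram from which the limited-angle acquisition is cut.
#'
#' @param s360 A [sinogram()] covering exactly 360 degrees.
#' @return A [sinogram()] covering 450 degrees; rows for `[360, 450)` are
#'   byte-identical copies of rows `[0, 90)`.
#' @export
extend_to_450 <- function(s360) {
  stopifnot(inherits(s360, "sinogram"))
  if (abs(coverage_deg(s360) - 360) > 1e-9)
    stop("input must cover exactly 360 degrees", call. = FALSE)
  n_copy <- as.integer(round(90 / s360$angle_step_deg))
  if (abs(n_copy * s360$angle_step_deg - 90) > 1e-9)
    stop("angular step must divide 90 degrees", call. = FALSE)
  vals <- rbind(s360$values, s360$values[seq_len(n_copy), , drop = FALSE])
  known <- if (!is.null(s360$known)) c(s360$known, s360$known[seq_len(n_copy)])
  sinogram(vals, s360$angle_step_deg, s360$angle_start, s360$bin_pitch_um, known)
}

#' Cut the limited-angle band out of a 450-degree sinogram
#'
#' Rows with angles in `[90, 360)` are replaced by 0 and marked missing in the
#' returned mask; rows in `[0, 90)` and `[360, 450)` are kept bit-exactly.
#'
#' @param s450 A [sinogram()] covering 450 degrees.
#' @return List with `sinogram` (masked values, `known` mask attached) and
#'   `mask` (logical, `TRUE` = known row).
#' @export
apply_la_mask <- function(s450) {
  stopifnot(inherits(s450, "sinogram"))
  if (abs(coverage_deg(s450) - 450) > 1e-9)
    stop("input must cover exactly 450 degrees", call. = FALSE)
  ang <- sinogram_angles(s450)
  known <- !(ang >= 90 - 1e-9 & ang < 360 - 1e-9)
  vals <- s450$values
  vals[!known, ] <- 0
  out <- sinogram(vals, s450$angle_step_deg, s450$angle_start,
                  s450$bin_pitch_um, known = known)
  list(sinogram = out, mask = known)
}

# bilinear resampling of a matrix to new dimensions, treating entries as
# samples of a continuous field at cell centres on [0, 1]^2
bilinear_resize <- function(m, nrow_out, ncol_out) {
  nr <- nrow(m); nc <- ncol(m)
  rf <- (seq_len(nrow_out) - 0.5) / nrow_out * nr + 0.5
  cf <- (seq_len(ncol_out) - 0.5) / ncol_out * nc + 0.5
  r0 <- pmin(pmax(floor(rf), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(cf), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(rf - r0, 0), 1); fc <- pmin(pmax(cf - c0, 0), 1)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  FR <- matrix(fr, nrow_out, ncol_out); FC <- matrix(fc, nrow_out, ncol_out, byrow = TRUE)
  (1 - FR) * (1 - FC) * a + (1 - FR) * FC * b + FR * (1 - FC) * d + FR * FC * e
}

#' Bilinear angular/radial resampling of a sinogram
#'
#' General-purpose resampling to `target_angles x target_bins` with metadata
#' rescaling (no architecture constraints; see [resize_for_ce()] for the
#' checked context-encoder variant). The `known` mask maps to output rows
#' whose source span is fully known.
#'
#' @param s A [sinogram()].
#' @param target_angles,target_bins Output dimensions.
#' @return A resized [sinogram()].
#' @export
resize_sinogram <- function(s, target_angles, target_bins = ncol(s$values)) {
  stopifnot(inherits(s, "sinogram"))
  na <- nrow(s$values); nb <- ncol(s$values)
  if (na < 2 || nb < 2 || target_angles < 2 || target_bins < 2)
    stop("degenerate sinogram dimensions", call. = FALSE)
  vals <- bilinear_resize(s$values, target_angles, target_bins)
  known <- NULL
  if (!is.null(s$known)) {
    lo <- (seq_len(target_angles) - 1) * na / target_angles
    hi <- seq_len(target_angles) * na / target_angles
    known <- vapply(seq_len(target_angles), function(a) {
      rows <- seq(max(1L, floor(lo[a] - 0.5) + 1L), min(na, ceiling(hi[a] + 0.5)))
      all(s$known[rows])
    }, logical(1))
  }
  sinogram(vals, s$angle_step_deg * na / target_angles, s$angle_start,
           s$bin_pitch_um * nb / target_bins, known = known,
           completed = s$completed)
}

#' Resize a sinogram to the context-encoder input dimensions
#'
#' Bilinear resampling to `target_angles x target_bins` (defaults 448 x 544;
#' both must be divisible by 16 so the encoder's four 2x down-samplings are
#' exact). Metadata are rescaled: the radial sampling becomes
#' `bin_pitch * n_bins_in / target_bins` and the angular step
#' `step * n_angles_in / target_angles` -- e.g. 541 bins at 75 um resample to
#' 544 bins at 74.586 um and 450 angles at 1 deg to 448 at 1.004 deg. The
#' `known` mask maps to rows whose source span contains no missing band;
#' straddling rows are marked missing.
#'
#' @param s A [sinogram()].
#' @param target_angles,target_bins Output dimensions (each within 2x of the
#'   input dimension, divisible by 16).
#' @return A resized [sinogram()].
#' @export
resize_for_ce <- function(s, target_angles = 448, target_bins = 544) {
  stopifnot(inherits(s, "sinogram"))
  na <- nrow(s$values); nb <- ncol(s$values)
  if (target_angles %% 16 != 0 || target_bins %% 16 != 0)
    stop("configuration error: CE dims must be divisible by 16", call. = FALSE)
  if (na < 2 || nb < 2) stop("degenerate sinogram dimensions", call. = FALSE)
  if (na > 2 * target_angles || na < target_angles / 2 ||
      nb > 2 * target_bins || nb < target_bins / 2)
    stop("input dims must be within 2x of the target", call. = FALSE)
  resize_sinogram(s, target_angles, target_bins)
}

#' Fold a 450-degree sinogram back to 360 degrees
#'
#' Inverse of [extend_to_450()] once the missing band has been completed: rows
#' in `[0, 90)` are replaced by the element-wise mean of the `[0, 90)` and
#' `[360, 450)` bands (they duplicate the same rays, so averaging is exact on
#' consistent data and halves prediction noise), and the output covers
#' `[0, 360)`. `fold = "keep-first"` keeps the `[0, 90)` band unchanged.
#'
#' @param s450 A [sinogram()] covering 450 degrees.
#' @param fold `"mean"` (default) or `"keep-first"`.
#' @return A [sinogram()] covering 360 degrees.
#' @export
fold_back_360 <- function(s450, fold = c("mean", "keep-first")) {
  fold <- match.arg(fold)
  stopifnot(inherits(s450, "sinogram"))
  if (abs(coverage_deg(s450) - 450) > 1e-9)
    stop("input must cover exactly 450 degrees", call. = FALSE)
  n360 <- as.integer(round(360 / s450$angle_step_deg))
  n_dup <- nrow(s450$values) - n360
  vals <- s450$values[seq_len(n360), , drop = FALSE]
  if (fold == "mean") {
    dup <- s450$values[n360 + seq_len(n_dup), , drop = FALSE]
    vals[seq_len(n_dup), ] <- (vals[seq_len(n_dup), , drop = FALSE] + dup) / 2
  }
  known <- if (!is.null(s450$known)) s450$known[seq_len(n360)]
  sinogram(vals, s450$angle_step_deg, s450$angle_start, s450$bin_pitch_um,
           known = known, completed = s450$completed)
}

#' Write / read sinograms (single or stacked) losslessly
#'
#' Values and all metadata round-trip bit-exactly through a self-describing
#' serialized container. A list of sinograms (a slice stack) is accepted and
#' returned as written.
#'
#' @param s A [sinogram()] or list of sinograms.
#' @param path File path (conventional extension `.sino.rds`).
#' @return `read_sinogram` returns the stored [sinogram()] or list;
#'   `write_sinogram` returns `path` invisibly.
#' @export
write_sinogram <- function(s, path) {
  ok <- inherits(s, "sinogram") ||
    (is.list(s) && length(s) > 0 && all(vapply(s, inherits, logical(1), "sinogram")))
  if (!ok) stop("'s' must be a sinogram or a list of sinograms", call. = FALSE)
  payload <- list(format = "lair-sinogram", version = 1L, data = s)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable sinogram file: ", path, call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, "lair-sinogram"))
    stop("format error: file lacks sinogram metadata", call. = FALSE)
  check1 <- function(x) {
    if (!inherits(x, "sinogram") || is.null(x$angle_step_deg))
      stop("format error: file lacks angle metadata", call. = FALSE)
    x
  }
  if (inherits(payload$data, "sinogram")) check1(payload$data)
  else lapply(payload$data, check1)
}
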