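#' Scan geometry for a rotating source-detector micro-CT system
#'
#' Describes the distances and detector sampling of a single-row (central
#' slice) acquisition. The flat-panel fan geometry (`beam = "fan_flat"`) is the
#' default; `"parallel"` rays are provided mainly for analytic test cases where
#' the Radon transform has closed forms.
#'
#' @param sod_mm Source-to-rotation-centre distance (mm).
#' @param sid_mm Source-to-detector distance (mm); must be >= `sod_mm`.
#' @param det_pitch_um Detector bin pitch (micrometres).
#' @param det_count Number of detector bins in the row.
#' @param beam `"fan_flat"` (flat equidistant detector) or `"parallel"`.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(sod_mm = 299, sid_mm = 325, det_pitch_um = 75, det_count = 864)
#' magnification(g)
#' isocenter_voxel_size(g)
#' @export
scan_geometry <- function(sod_mm, sid_mm, det_pitch_um, det_count,
                          beam = c("fan_flat", "parallel")) {
  beam <- match.arg(beam)
  if (!is.numeric(sod_mm) || length(sod_mm) != 1L || !is.finite(sod_mm) || sod_mm <= 0)
    stop("invalid geometry: 'sod_mm' must be a single positive number", call. = FALSE)
  if (!is.numeric(sid_mm) || length(sid_mm) != 1L || !is.finite(sid_mm) || sid_mm < sod_mm)
    stop("invalid geometry: 'sid_mm' must be a single number >= sod_mm", call. = FALSE)
  if (!is.numeric(det_pitch_um) || det_pitch_um <= 0)
    stop("invalid geometry: 'det_pitch_um' must be positive", call. = FALSE)
  det_count <- as.integer(det_count)
  if (is.na(det_count) || det_count < 1L)
    stop("invalid geometry: 'det_count' must be >= 1", call. = FALSE)
  structure(
    list(sod_mm = as.numeric(sod_mm), sid_mm = as.numeric(sid_mm),
         det_pitch_um = as.numeric(det_pitch_um), det_count = det_count,
         beam = beam),
    class = "scan_geometry")
}

print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s beam, SOD %g mm, SID %g mm, %d bins @ %g um (M = %.4f)\n",
              x$beam, x$sod_mm, x$sid_mm, x$det_count, x$det_pitch_um, magnification(x)))
  invisible(x)
}

#' Geometric magnification SID/SOD
#'
#' @param geom A [scan_geometry()].
#' @return Dimensionless magnification ratio.
#' @export
magnification <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  geom$sid_mm / geom$sod_mm
}

#' Detector sampling demagnified to the rotation centre
#'
#' The detector pitch divided by the magnification, i.e. the natural voxel
#' size of a reconstruction on the isocentre plane. For the 75 um flat panel
#' at SOD 299 mm / SID 325 mm this is 69.00 um; moving the object close to the
#' source (SOD 49 mm, SID 211.1 mm) gives 17.4088 um.
#'
#' @inheritParams magnification
#' @return Voxel size in micrometres.
#' @export
isocenter_voxel_size <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  geom$det_pitch_um * geom$sod_mm / geom$sid_mm
}

#' Transaxial field of view at the isocentre
#'
#' Width of detector row demagnified to the rotation centre,
#' `det_count * det_pitch * SOD / SID`, in mm.
#'
#' @inheritParams magnification
#' @return Field-of-view width in mm.
#' @export
fov_mm <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  geom$det_count * isocenter_voxel_size(geom) / 1000
}

#' Acquisition protocol: angular step and coverage
#'
#' The three study protocols are limited-angle (`LA`, 1 deg/view over 90 deg),
#' densely-sampled full coverage (`DSFC`, 1 deg/view over 360 deg) and
#' loosely-sampled full coverage (`LSFC`, 5 deg/view over 360 deg).
#'
#' @param step_deg Angular step between projections (degrees).
#' @param coverage_deg Total angular coverage (degrees); must be an integer
#'   multiple of `step_deg`.
#' @param label One of `"LA"`, `"DSFC"`, `"LSFC"`, `"custom"`.
#' @return An object of class `acquisition_protocol`.
#' @examples
#' length(projection_angles(protocol_la()))    # 90
#' length(projection_angles(protocol_dsfc()))  # 360
#' length(projection_angles(protocol_lsfc()))  # 72
#' @export
acquisition_protocol <- function(step_deg, coverage_deg,
                                 label = c("custom", "LA", "DSFC", "LSFC")) {
  label <- match.arg(label)
  if (!is.numeric(step_deg) || step_deg <= 0)
    stop("configuration error: 'step_deg' must be positive", call. = FALSE)
  if (!is.numeric(coverage_deg) || coverage_deg <= 0)
    stop("configuration error: 'coverage_deg' must be positive", call. = FALSE)
  n <- coverage_deg / step_deg
  if (abs(n - round(n)) > 1e-9)
    stop("configuration error: 'coverage_deg' must be an integer multiple of 'step_deg'",
         call. = FALSE)
  structure(list(step_deg = as.numeric(step_deg),
                 coverage_deg = as.numeric(coverage_deg), label = label),
            class = "acquisition_protocol")
}

#' @rdname acquisition_protocol
#' @export
protocol_la <- function() acquisition_protocol(1, 90, "LA")

#' @rdname acquisition_protocol
#' @export
protocol_dsfc <- function() acquisition_protocol(1, 360, "DSFC")

#' @rdname acquisition_protocol
#' @export
protocol_lsfc <- function() acquisition_protocol(5, 360, "LSFC")

print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s: %g deg/view, %g deg coverage (%d views)\n",
              x$label, x$step_deg, x$coverage_deg,
              length(projection_angles(x))))
  invisible(x)
}

#' Projection angles of a protocol
#'
#' Angles are in degrees, counter-clockwise, starting at 0 with 0 along the
#' +x axis of the image grid; the source-detector pair rotates, the object is
#' fixed. The last angle is `coverage_deg - step_deg`.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of `coverage_deg / step_deg` strictly increasing angles.
#' @export
projection_angles <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  n <- as.integer(round(protocol$coverage_deg / protocol$step_deg))
  seq(0, by = protocol$step_deg, length.out = n)
}

#' Read geometry and protocol from a YAML/JSON configuration file
#'
#' Recognised keys: `sod_mm`, `sid_mm`, `det_pitch_um`, `det_count`, `beam`,
#' `step_deg`, `coverage_deg`, `label`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `geometry` ([scan_geometry()]) and
#'   `protocol` ([acquisition_protocol()]; `NULL` if angular keys absent).
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("sod_mm", "sid_mm", "det_pitch_um", "det_count")
  if (!all(need %in% names(cfg)))
    stop("configuration error: missing keys ",
         paste(setdiff(need, names(cfg)), collapse = ", "), call. = FALSE)
  geom <- scan_geometry(cfg$sod_mm, cfg$sid_mm, cfg$det_pitch_um, cfg$det_count,
                        beam = if (is.null(cfg$beam)) "fan_flat" else cfg$beam)
  proto <- NULL
  if (!is.null(cfg$step_deg) && !is.null(cfg$coverage_deg)) {
    proto <- acquisition_protocol(cfg$step_deg, cfg$coverage_deg,
                                  label = if (is.null(cfg$label)) "custom" else cfg$label)
  }
  list(geometry = geom, protocol = proto)
}
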