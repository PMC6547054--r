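#' Acquisition metadata for one weighted contrast
#'
#' Describes one spoiled gradient-echo acquisition. Internal canonical units
#' are milliseconds (TR, TE) and degrees (flip angle); JSON sidecars use the
#' BIDS conventions (seconds, degrees) and are converted on read/write.
#'
#' @param contrast one of `"PDw"`, `"T1w"`, `"MTw"`.
#' @param flip_angle nominal excitation flip angle in degrees, in (0, 90].
#' @param tr repetition time in ms.
#' @param echo_times echo times in ms, strictly increasing, all > 0.
#' @param mt_pulse logical; whether an off-resonance MT pulse is applied.
#'   Must be `TRUE` iff `contrast == "MTw"`. Defaults accordingly.
#' @return an object of class `acq_metadata`.
#' @export
acq_metadata <- function(contrast, flip_angle, tr, echo_times,
                         mt_pulse = identical(contrast, "MTw")) {
  contrast <- match.arg(contrast, c("PDw", "T1w", "MTw"))
  flip_angle <- as.numeric(flip_angle)
  tr <- as.numeric(tr)
  echo_times <- as.numeric(echo_times)
  if (!is.finite(tr) || tr <= 0) stop("acq_metadata: tr must be > 0")
  if (length(echo_times) < 1L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0))
    stop("acq_metadata: echo_times must be positive and strictly increasing")
  if (!is.finite(flip_angle) || flip_angle <= 0 || flip_angle > 90)
    stop("acq_metadata: flip_angle must be in (0, 90] degrees")
  if (!identical(mt_pulse, contrast == "MTw"))
    stop("acq_metadata: mt_pulse must be TRUE iff contrast is MTw")
  structure(list(contrast = contrast, flip_angle = flip_angle, tr = tr,
                 echo_times = echo_times, mt_pulse = mt_pulse),
            class = "acq_metadata")
}

is_acq_metadata <- function(x) inherits(x, "acq_metadata")

flip_rad <- function(meta) meta$flip_angle * pi / 180

#' Convert a BIDS-style sidecar list to acquisition metadata
#'
#' Sidecar fields: `RepetitionTime` (s), `EchoTime` (s, scalar for the
#' volume's own echo) or `EchoTimes` (s, full train), `FlipAngle` (degrees),
#' `ContrastLabel` (PDw/T1w/MTw) and `MTState` (logical, falls back to the
#' contrast label when absent).
#'
#' @param sidecar named list as parsed from JSON.
#' @param strict error on missing required fields (otherwise return `NULL`).
#' @return [acq_metadata] or `NULL`.
#' @export
metadata_from_sidecar <- function(sidecar, strict = TRUE) {
  need <- function(field) {
    v <- sidecar[[field]]
    if (is.null(v)) {
      if (strict) stop("metadata_from_sidecar: missing required field '",
                       field, "'")
      return(NULL)
    }
    v
  }
  tr <- need("RepetitionTime")
  fa <- need("FlipAngle")
  te <- sidecar[["EchoTimes"]]
  if (is.null(te)) te <- need("EchoTime")
  ctr <- need("ContrastLabel")
  if (is.null(tr) || is.null(fa) || is.null(te) || is.null(ctr)) return(NULL)
  mt <- sidecar[["MTState"]]
  if (is.null(mt)) mt <- identical(ctr, "MTw")
  acq_metadata(contrast = ctr, flip_angle = fa,
               tr = 1000 * as.numeric(tr),
               echo_times = 1000 * sort(unlist(te)),
               mt_pulse = isTRUE(mt))
}

#' @rdname metadata_from_sidecar
#' @param meta an [acq_metadata].
#' @param echo 1-based echo index whose `EchoTime` the sidecar describes
#'   (`NULL` writes the full `EchoTimes` list only).
#' @export
sidecar_from_metadata <- function(meta, echo = NULL) {
  stopifnot(is_acq_metadata(meta))
  out <- list(
    RepetitionTime = meta$tr / 1000,
    FlipAngle = meta$flip_angle,
    EchoTimes = meta$echo_times / 1000,
    ContrastLabel = meta$contrast,
    MTState = meta$mt_pulse
  )
  if (!is.null(echo)) out$EchoTime <- meta$echo_times[echo] / 1000
  out
}

#' Multi-echo series: one weighted contrast
#'
#' @param meta an [acq_metadata].
#' @param volumes list of [qvol], one per echo, in echo-time order; all on
#'   an identical grid.
#' @param source optional source file basename used to derive output names.
#' @return object of class `mpm_series`.
#' @export
mpm_series <- function(meta, volumes, source = NULL) {
  stopifnot(is_acq_metadata(meta))
  if (length(volumes) != length(meta$echo_times))
    stop("mpm_series: number of volumes must equal number of echo times")
  if (!all(vapply(volumes, is_qvol, logical(1))))
    stop("mpm_series: volumes must be qvol objects")
  assert_common_grid(volumes)
  structure(list(meta = meta, volumes = volumes, source = source),
            class = "mpm_series")
}

is_mpm_series <- function(x) inherits(x, "mpm_series")

#' @export
print.mpm_series <- function(x, ...) {
  cat(sprintf("mpm_series %s: %d echoes, TR %.3g ms, flip %.3g deg\n",
              x$meta$contrast, length(x$volumes), x$meta$tr,
              x$meta$flip_angle))
  invisible(x)
}

#' Read a multi-echo series from NIfTI files
#'
#' @param paths NIfTI file paths, one per echo. Sidecars must be present for
#'   at least the first echo unless `meta` is supplied.
#' @param meta optional [acq_metadata] overriding the sidecars.
#' @return an [mpm_series]; `source` is the basename of the first file.
#' @export
read_series <- function(paths, meta = NULL) {
  if (length(paths) < 1L) stop("read_series: no paths")
  vols <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    r <- read_volume(paths[i], need_metadata = is.null(meta))
    vols[[i]] <- r$volume
    if (is.null(meta) && i == 1L) first_meta <- r$meta
  }
  if (is.null(meta)) {
    # per-echo sidecars carry their own EchoTime first in the list
    sc <- jsonlite::read_json(sidecar_path(paths[1]))
    te_all <- if (!is.null(sc$EchoTimes)) 1000 * unlist(sc$EchoTimes) else {
      vapply(paths, function(p) {
        s <- jsonlite::read_json(sidecar_path(p))
        1000 * as.numeric(s$EchoTime)
      }, numeric(1))
    }
    meta <- acq_metadata(first_meta$contrast, first_meta$flip_angle,
                         first_meta$tr, te_all)
  }
  src <- sub("\\.nii(\\.gz)?$", "", basename(paths[1]))
  mpm_series(meta, vols, source = src)
}
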