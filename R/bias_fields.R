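#' Transmit bias field
#'
#' A multiplicative transmit (B1+) field: `ft = 1` means the local flip
#' angle equals the nominal one. Stored internally as a fraction; exported
#' and imported in percent units (100 = nominal).
#'
#' @param ft [qvol] or array of the field as a fraction.
#' @param source one of `"AFI"`, `"precomputed"`, `"unity"`.
#' @return object of class `transmit_field` with elements `ft` ([qvol]),
#'   `mask` ([qvol]) and `source`.
#' @export
transmit_field <- function(ft, source = c("precomputed", "AFI", "unity"),
                           mask = NULL) {
  source <- match.arg(source)
  if (!is_qvol(ft)) ft <- qvol(as_vol_array(ft))
  if (is.null(mask)) mask <- vol_like((ft$data > 0) * 1, ft)
  structure(list(ft = ft, mask = mask, source = source),
            class = "transmit_field")
}

#' @rdname transmit_field
#' @param x a `transmit_field`.
#' @export
ft_as_pu <- function(x) {
  stopifnot(inherits(x, "transmit_field"))
  vol_like(100 * x$ft$data, x$ft)
}

#' Actual-flip-angle-imaging pair
#'
#' Two spoiled volumes acquired with interleaved repetition times
#' `TR1 < TR2` at a common nominal flip angle; the ratio `S2/S1` encodes the
#' local flip angle.
#'
#' @param s1,s2 [qvol]: the TR1- and TR2-weighted volumes (common grid).
#' @param tr1,tr2 repetition times in ms, `tr2 > tr1 > 0`.
#' @param alpha_nominal nominal flip angle in degrees (> 0).
#' @return object of class `afi_pair`.
#' @export
afi_pair <- function(s1, s2, tr1, tr2, alpha_nominal) {
  if (!is_qvol(s1)) s1 <- qvol(as_vol_array(s1))
  if (!is_qvol(s2)) s2 <- qvol(as_vol_array(s2))
  assert_common_grid(s1, s2)
  if (!(tr1 > 0) || !(tr2 / tr1 > 1))
    stop("afi_pair: need tr2 > tr1 > 0")
  if (!(alpha_nominal > 0)) stop("afi_pair: alpha_nominal must be > 0")
  structure(list(s1 = s1, s2 = s2, tr1 = tr1, tr2 = tr2,
                 alpha_nominal = alpha_nominal),
            class = "afi_pair")
}

#' B1 transmit field from an AFI pair
#'
#' Inverts the standard actual-flip-angle relation under ideal spoiling:
#' with `r = S2/S1` and `n = TR2/TR1`,
#' \deqn{\cos\alpha_{actual} = (r n - 1) / (n - r), \quad
#'   f_T = \alpha_{actual} / \alpha_{nominal}.}
#' Voxels where `S1 <= 0` or the cosine argument falls outside `[-1, 1]`
#' are masked invalid. The field is smoothed (Gaussian, `fwhm` mm) over the
#' valid region before export; `fwhm = 0` disables smoothing.
#'
#' @param pair an [afi_pair()].
#' @param fwhm smoothing kernel FWHM in mm (default 8).
#' @return a [transmit_field] (source `"AFI"`), plus an anatomical
#'   reference: element `ref` is the mean AFI magnitude.
#' @export
afi_to_ft <- function(pair, fwhm = 8) {
  stopifnot(inherits(pair, "afi_pair"))
  n <- pair$tr2 / pair$tr1
  s1 <- pair$s1$data
  s2 <- pair$s2$data
  r <- array(NA_real_, dim(s1))
  pos <- s1 > 0
  r[pos] <- s2[pos] / s1[pos]
  cosa <- (r * n - 1) / (n - r)
  ok <- pos & is.finite(cosa) & cosa >= -1 & cosa <= 1
  alpha <- array(NA_real_, dim(s1))
  alpha[ok] <- acos(cosa[ok])
  ft <- alpha / (pair$alpha_nominal * pi / 180)
  ft[!ok] <- NA_real_
  if (fwhm > 0) {
    # smooth within the valid region: normalised masked convolution
    w <- ok * 1
    ftz <- ft; ftz[!ok] <- 0
    num <- gaussian_smooth(vol_like(ftz * w, pair$s1), fwhm)$data
    den <- gaussian_smooth(vol_like(w, pair$s1), fwhm)$data
    ft <- ifelse(den > 1e-6, num / den, NA_real_)
    ft[!ok] <- NA_real_
  }
  ftv <- vol_like(ifelse(is.na(ft), 0, ft), pair$s1)
  tf <- transmit_field(ftv, source = "AFI",
                       mask = vol_like(ok * 1, pair$s1))
  tf$ref <- vol_like((s1 + s2) / 2, pair$s1)
  tf
}

#' Forward AFI signal model (simulation)
#'
#' Simulates the interleaved two-TR steady-state signal pair
#' \deqn{S_i \propto \sin\alpha \,
#'   (1 - E_j + (1 - E_i) E_j \cos\alpha) / (1 - E_1 E_2 \cos^2\alpha)}
#' in the short-TR regime `E_i = 1 - TR_i R1` in which the actual-flip-angle
#' relation is algebraically exact (the regime AFI protocols are designed
#' for, TR << T1).
#'
#' @param alpha actual flip angle in radians (array or scalar).
#' @param tr1,tr2 repetition times in ms.
#' @param r1 longitudinal relaxation rate in 1/s.
#' @param A signal scale (a.u.).
#' @return list of arrays `s1`, `s2`.
#' @export
afi_simulate <- function(alpha, tr1, tr2, r1 = 1, A = 1000) {
  t1 <- tr1 * r1 / 1000
  t2 <- tr2 * r1 / 1000
  e1 <- 1 - t1
  e2 <- 1 - t2
  den <- 1 - e1 * e2 * cos(alpha)^2
  s1 <- A * sin(alpha) * (t2 + t1 * cos(alpha)) / den
  s2 <- A * sin(alpha) * (t1 + t2 * cos(alpha)) / den
  list(s1 = s1, s2 = s2)
}

#' Load a pre-computed B1 map
#'
#' Reads a transmit-field NIfTI produced outside the package. Units are
#' auto-detected from the median over positive voxels: a median near 100
#' means percent units, near 1 means fraction; anything else is rejected as
#' ambiguous.
#'
#' @param path NIfTI file.
#' @return a [transmit_field] (fraction, source `"precomputed"`).
#' @export
load_precomputed_ft <- function(path) {
  v <- read_volume(path)$volume
  med <- stats::median(v$data[v$data > 0])
  if (is.finite(med) && med >= 100 * 0.3 && med <= 100 * 3) {
    f <- v$data / 100
  } else if (is.finite(med) && med >= 0.3 && med <= 3) {
    f <- v$data
  } else {
    stop("load_precomputed_ft: median ", signif(med, 3),
         " matches neither percent units nor fraction; units ambiguous")
  }
  transmit_field(vol_like(f, v), source = "precomputed")
}

#' Receive sensitivity field from a head/body coil pair
#'
#' The receive field is estimated as the ratio of smoothed head-coil to
#' smoothed body-coil images, `fR = smooth(head) / smooth(body)`, masked
#' where the smoothed body-coil reference falls below `threshold` times its
#' maximum. The body coil serves as reference as measured; its own receive
#' inhomogeneity is not corrected for (a known limitation recorded in
#' provenance by the pipeline).
#'
#' @param head,body [qvol] on a common grid.
#' @param fwhm Gaussian kernel FWHM in mm (default 12).
#' @param threshold relative body-coil threshold in (0, 1).
#' @return list with `map` ([qvol], a.u.) and `mask`.
#' @export
receive_from_pair <- function(head, body, fwhm = 12, threshold = 0.05) {
  if (!is_qvol(head)) head <- qvol(as_vol_array(head))
  if (!is_qvol(body)) body <- qvol(as_vol_array(body))
  assert_common_grid(head, body)
  if (all(body$data == 0)) stop("receive_from_pair: body image is all zero")
  sh <- gaussian_smooth(head, fwhm)$data
  sb <- gaussian_smooth(body, fwhm)$data
  ok <- sb > threshold * max(sb)
  fr <- array(0, dim(sh))
  fr[ok] <- sh[ok] / sb[ok]
  list(map = vol_like(fr, head), mask = vol_like(ok * 1, head))
}

#' Apply receive-sensitivity correction
#'
#' Divides the data voxelwise by the matching receive field. `mode =
#' "single"` uses one field for every contrast (valid when inter-contrast
#' motion is small); `mode = "per_contrast"` requires one field per
#' contrast and is robust to motion-induced changes of the sensitivity
#' profile between contrasts.
#'
#' @param x an [mpm_series], a named list of series, or a [qvol]/array
#'   intercept map.
#' @param fr a [qvol]/array (mode `"single"`), or a named list of fields
#'   keyed by contrast (mode `"per_contrast"`). Entries may also be
#'   `receive_from_pair()` results.
#' @param mode `"single"` or `"per_contrast"`.
#' @return corrected object of the same shape as `x`.
#' @export
apply_receive_correction <- function(x, fr,
                                     mode = c("single", "per_contrast")) {
  mode <- match.arg(mode)
  get_field <- function(ctr) {
    f <- if (mode == "single") {
      if (is.list(fr) && !is_qvol(fr) && !is.null(fr$map)) fr$map else fr
    } else {
      if (!is.list(fr) || is.null(fr[[ctr]]))
        stop("apply_receive_correction: per-contrast mode but no receive ",
             "field for contrast ", ctr)
      f <- fr[[ctr]]
      if (is.list(f) && !is_qvol(f) && !is.null(f$map)) f$map else f
    }
    as_vol_array(f)
  }
  divide <- function(vol, f) {
    d <- vol$data
    out <- array(0, dim(d))
    ok <- f > 0
    out[ok] <- d[ok] / f[ok]
    vol_like(out, vol)
  }
  if (is_mpm_series(x)) {
    f <- get_field(x$meta$contrast)
    x$volumes <- lapply(x$volumes, divide, f = f)
    return(x)
  }
  if (is.list(x) && all(vapply(x, is_mpm_series, logical(1)))) {
    return(lapply(x, apply_receive_correction, fr = fr, mode = mode))
  }
  if (mode == "per_contrast")
    stop("apply_receive_correction: per-contrast mode needs series input")
  v <- if (is_qvol(x)) x else qvol(as_vol_array(x))
  divide(v, get_field(NULL))
}
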