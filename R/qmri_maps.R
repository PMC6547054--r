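#' Longitudinal relaxation rate from dual-flip-angle intercepts
#'
#' Computes R1 from the TE=0 intercepts of a low-angle (PDw) and a
#' high-angle (T1w) acquisition with the rational small-TR/small-angle
#' approximation
#' \deqn{R1 = \frac{1}{2}\,
#'   \frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
#'        {S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}}
#' with local flip angles `alpha_c = fT * alpha_nominal,c` in radians and TR
#' in ms; the result is converted to 1/s. Voxels with a non-positive
#' denominator (or non-positive input signal) are masked invalid.
#'
#' Unit regime: this formula and [compute_amplitude()] work in ms and
#' radians; [compute_mt_sat()] uses seconds for its `R1 * TR` term. The
#' conversions are internal; all R1 maps exposed by this package are 1/s.
#'
#' @param s_pd0,s_t10 TE=0 intercept maps ([qvol] or array), a.u.
#' @param meta_pd,meta_t1 [acq_metadata] of the two acquisitions. Their
#'   effective flip angles must differ.
#' @param ft transmit bias field (array, [qvol], or [transmit_field];
#'   1 = nominal). `NULL` means nominal flip angles everywhere.
#' @return list with `map` ([qvol], 1/s) and `mask` ([qvol], 1 = valid).
#' @export
compute_r1 <- function(s_pd0, s_t10, meta_pd, meta_t1, ft = NULL) {
  x <- dual_angle_inputs(s_pd0, s_t10, meta_pd, meta_t1, ft)
  num <- x$s_t1 * x$a_t1 / x$tr_t1 - x$s_pd * x$a_pd / x$tr_pd
  den <- x$s_pd / x$a_pd - x$s_t1 / x$a_t1
  r1 <- 0.5 * num / den * 1000  # 1/ms -> 1/s
  # validity: a physically meaningful (positive, finite) rate; this is
  # symmetric under swapping the two inputs, which negates num and den
  ok <- x$ok & den != 0 & is.finite(r1) & r1 > 0
  r1[!ok] <- 0
  list(map = vol_like(r1, x$tmpl), mask = vol_like(ok * 1, x$tmpl))
}

#' Apparent signal amplitude from dual-flip-angle intercepts
#'
#' \deqn{A = S_{PD} S_{T1}
#'   \frac{TR_{PD}\alpha_{T1}/\alpha_{PD} - TR_{T1}\alpha_{PD}/\alpha_{T1}}
#'        {S_{T1} TR_{PD}\alpha_{T1} - S_{PD} TR_{T1}\alpha_{PD}}}
#' with B1-corrected local angles; A is proportional to proton density and
#' is calibrated to percent units by [calibrate_pd()].
#'
#' @inheritParams compute_r1
#' @return list with `map` ([qvol], a.u.) and `mask`.
#' @export
compute_amplitude <- function(s_pd0, s_t10, meta_pd, meta_t1, ft = NULL) {
  x <- dual_angle_inputs(s_pd0, s_t10, meta_pd, meta_t1, ft)
  num <- x$tr_pd * x$a_t1 / x$a_pd - x$tr_t1 * x$a_pd / x$a_t1
  den <- x$s_t1 * x$tr_pd * x$a_t1 - x$s_pd * x$tr_t1 * x$a_pd
  ok <- x$ok & abs(den) > .Machine$double.eps * (x$s_pd + x$s_t1)
  amp <- x$s_pd * x$s_t1 * num / den
  amp[!ok] <- 0
  list(map = vol_like(amp, x$tmpl), mask = vol_like(ok * 1, x$tmpl))
}

# shared preparation for the two dual-angle formulas
dual_angle_inputs <- function(s_pd0, s_t10, meta_pd, meta_t1, ft) {
  stopifnot(is_acq_metadata(meta_pd), is_acq_metadata(meta_t1))
  tmpl <- if (is_qvol(s_pd0)) s_pd0 else if (is_qvol(s_t10)) s_t10 else NULL
  s_pd <- as_vol_array(s_pd0)
  s_t1 <- as_vol_array(s_t10)
  if (!identical(dim(s_pd), dim(s_t1)))
    stop("dual-angle inputs not on a common grid")
  ftv <- ft_fraction(ft, dim(s_pd))
  a_pd <- ftv * flip_rad(meta_pd)
  a_t1 <- ftv * flip_rad(meta_t1)
  if (isTRUE(all.equal(meta_pd$flip_angle, meta_t1$flip_angle)))
    stop("degenerate protocol: identical effective flip angles, ",
         "the dual-angle system is unsolvable")
  ok <- s_pd > 0 & s_t1 > 0 & a_pd > 0 & a_t1 > 0 &
    a_pd < pi / 2 & a_t1 < pi / 2
  if (is.null(tmpl)) tmpl <- qvol(s_pd)
  list(s_pd = s_pd, s_t1 = s_t1, a_pd = a_pd, a_t1 = a_t1,
       tr_pd = meta_pd$tr, tr_t1 = meta_t1$tr, ok = ok, tmpl = tmpl)
}

# normalise the many accepted fT representations to an array (1 = nominal)
ft_fraction <- function(ft, dims) {
  if (is.null(ft)) return(array(1, dims))
  if (inherits(ft, "transmit_field")) ft <- ft$ft
  f <- as_vol_array(ft)
  if (length(f) == 1L) f <- array(f, dims)
  if (!identical(dim(f), dims))
    stop("transmit field not on the data grid")
  f
}

#' Magnetisation transfer saturation
#'
#' The per-excitation saturation delta (percent units) induced by the MT
#' pulse, from the MTw TE=0 intercept and previously computed A and R1:
#' \deqn{\delta = 100\left[(A\alpha_{MT}/S_{MT} - 1) R1 \, TR_{MT}
#'   - \alpha_{MT}^2/2\right]}
#' with the local `alpha_MT` in radians, R1 in 1/s and TR in seconds.
#' Unlike the MT ratio, delta is (to first order) free of T1 and B1 bias;
#' the residual B1 dependence is reduced further by [b1_correct_mt()].
#'
#' @param s_mt0 MTw TE=0 intercept map ([qvol] or array), a.u.
#' @param amplitude A map from [compute_amplitude()] (`$map` or qvol/array).
#' @param r1 R1 map in 1/s (`$map` of [compute_r1()], qvol or array).
#' @param meta_mt [acq_metadata] of the MTw acquisition.
#' @inheritParams compute_r1
#' @return list with `map` ([qvol], p.u.) and `mask` (voxels with
#'   `S_MT <= 0` or invalid A/R1 are masked).
#' @export
compute_mt_sat <- function(s_mt0, amplitude, r1, meta_mt, ft = NULL) {
  stopifnot(is_acq_metadata(meta_mt), meta_mt$mt_pulse)
  if (is.list(amplitude) && !is_qvol(amplitude)) amplitude <- amplitude$map
  if (is.list(r1) && !is_qvol(r1)) r1 <- r1$map
  tmpl <- if (is_qvol(s_mt0)) s_mt0 else NULL
  s_mt <- as_vol_array(s_mt0)
  a <- as_vol_array(amplitude)
  r1v <- as_vol_array(r1)
  ftv <- ft_fraction(ft, dim(s_mt))
  alpha <- ftv * flip_rad(meta_mt)
  tr_s <- meta_mt$tr / 1000
  ok <- s_mt > 0 & a > 0 & r1v > 0
  delta <- 100 * ((a * alpha / pmax(s_mt, .Machine$double.xmin) - 1) *
                    r1v * tr_s - alpha^2 / 2)
  delta[!ok] <- 0
  if (is.null(tmpl)) tmpl <- qvol(s_mt)
  list(map = vol_like(delta, tmpl), mask = vol_like(ok * 1, tmpl))
}

#' Empirical B1 correction of MT saturation
#'
#' Applies the residual transmit-field correction
#' \deqn{\delta_{corr} = \delta (1 - C) / (1 - C f_T)}
#' voxelwise. `C = 0.4` is the conventional heuristic calibration constant
#' for 3T MPM protocols; with `C = 0` or nominal transmit field the
#' correction is the identity.
#'
#' @param mt_sat MT saturation map ([qvol] or array, p.u.), or the list
#'   returned by [compute_mt_sat()].
#' @param ft transmit field (1 = nominal).
#' @param C correction constant in `[0, 1)`.
#' @return list with `map` and `mask` (voxels with `C * fT >= 1` masked).
#' @export
b1_correct_mt <- function(mt_sat, ft, C = 0.4) {
  if (!is.finite(C) || C < 0 || C >= 1) stop("b1_correct_mt: C must be in [0,1)")
  if (is.list(mt_sat) && !is_qvol(mt_sat)) mt_sat <- mt_sat$map
  tmpl <- if (is_qvol(mt_sat)) mt_sat else NULL
  d <- as_vol_array(mt_sat)
  ftv <- ft_fraction(ft, dim(d))
  den <- 1 - C * ftv
  ok <- den > 0
  out <- d * (1 - C) / den
  out[!ok] <- 0
  if (is.null(tmpl)) tmpl <- qvol(d)
  list(map = vol_like(out, tmpl), mask = vol_like(ok * 1, tmpl))
}

#' Imperfect-spoiling correction coefficients
#'
#' Protocol-specific polynomials `Acoef(fT)` (ms) and `Bcoef(fT)`
#' (dimensionless) correcting the apparent T1 for incomplete transverse
#' spoiling: `T1_corr = Acoef(fT) + Bcoef(fT) * T1_app`. Coefficients are
#' supplied per protocol (ascending powers of fT); the identity is
#' `spoiling_coefficients(0, 1)`. By default the correction is disabled
#' ([apply_spoiling_correction()] with `coeffs = NULL`).
#'
#' @param acoef numeric vector, ascending polynomial coefficients of
#'   `Acoef(fT)` in ms.
#' @param bcoef ascending polynomial coefficients of `Bcoef(fT)`.
#' @param protocol optional character tag naming the protocol the
#'   coefficients were computed for.
#' @return object of class `spoiling_coefficients`.
#' @export
spoiling_coefficients <- function(acoef = 0, bcoef = 1, protocol = "") {
  acoef <- as.numeric(acoef); bcoef <- as.numeric(bcoef)
  probe <- seq(0.5, 1.5, by = 0.25)
  if (any(!is.finite(polyval(acoef, probe))) ||
      any(!is.finite(polyval(bcoef, probe))))
    stop("spoiling_coefficients: polynomials must be finite on [0.5, 1.5]")
  structure(list(acoef = acoef, bcoef = bcoef, protocol = protocol),
            class = "spoiling_coefficients")
}

polyval <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' @rdname spoiling_coefficients
#' @param r1_app apparent R1 map (1/s; [qvol], array, or `compute_r1()`
#'   result list).
#' @param ft transmit field (1 = nominal).
#' @param coeffs a `spoiling_coefficients` object, or `NULL` to disable the
#'   correction (the default: output equals input).
#' @return list with `map` (R1 in 1/s), `mask` and `enabled`.
#' @export
apply_spoiling_correction <- function(r1_app, ft = NULL, coeffs = NULL) {
  if (is.list(r1_app) && !is_qvol(r1_app)) r1_app <- r1_app$map
  tmpl <- if (is_qvol(r1_app)) r1_app else NULL
  r1 <- as_vol_array(r1_app)
  if (is.null(tmpl)) tmpl <- qvol(r1)
  if (is.null(coeffs)) {
    return(list(map = vol_like(r1, tmpl),
                mask = vol_like(array(1, dim(r1)), tmpl), enabled = FALSE))
  }
  stopifnot(inherits(coeffs, "spoiling_coefficients"))
  ftv <- ft_fraction(ft, dim(r1))
  pos <- r1 > 0
  t1_app <- array(0, dim(r1))
  t1_app[pos] <- 1000 / r1[pos]  # ms
  t1_corr <- polyval(coeffs$acoef, ftv) + polyval(coeffs$bcoef, ftv) * t1_app
  ok <- pos & t1_corr > 0
  out <- array(0, dim(r1))
  out[ok] <- 1000 / t1_corr[ok]
  list(map = vol_like(out, tmpl), mask = vol_like(ok * 1, tmpl),
       enabled = TRUE)
}

#' Calibrate the amplitude map to percent-unit proton density
#'
#' Global multiplicative calibration: `PD = A * target / mean(A[mask])`.
#' With a user-supplied (typically white-matter) mask the conventional
#' target is 69 p.u.; without a mask the map is scaled so its mean over the
#' validity mask is 100 p.u. and must be read as a relative map. The caller
#' is responsible for receive-bias correction of A beforehand.
#'
#' @param amplitude A map ([qvol], array, or [compute_amplitude()] result).
#' @param mask logical/0-1 array or [qvol]: calibration region. `NULL`
#'   means all voxels with `A > 0`.
#' @param target calibration target in p.u.; default 69 with a mask,
#'   100 without.
#' @return list with `map` ([qvol], p.u.), `target`, `calibrated`
#'   (`FALSE` when no mask was supplied, i.e. relative scaling).
#' @export
calibrate_pd <- function(amplitude, mask = NULL, target = NULL) {
  if (is.list(amplitude) && !is_qvol(amplitude)) amplitude <- amplitude$map
  tmpl <- if (is_qvol(amplitude)) amplitude else NULL
  a <- as_vol_array(amplitude)
  calibrated <- !is.null(mask)
  if (is.null(target)) target <- if (calibrated) 69 else 100
  m <- if (is.null(mask)) a > 0 else as_vol_array(mask) > 0
  if (!any(m)) stop("calibrate_pd: empty calibration mask")
  mu <- mean(a[m])
  if (!is.finite(mu) || mu == 0)
    stop("calibrate_pd: calibration mean is zero or non-finite")
  if (is.null(tmpl)) tmpl <- qvol(a)
  list(map = vol_like(a * (target / mu), tmpl), target = target,
       calibrated = calibrated)
}
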