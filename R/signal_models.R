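#' Spoiled gradient-echo signal models
#'
#' `ernst_signal()` is the steady-state FLASH signal
#' \deqn{S = A \sin\alpha \, (1 - E_1) / (1 - \cos\alpha \, E_1),
#'   \quad E_1 = e^{-TR \cdot R1}}
#' with `alpha` in radians, `TR` in ms and `R1` in 1/s (so the exponent uses
#' `TR * R1 / 1000`). All arguments recycle voxelwise.
#'
#' `mt_flash_signal()` is the small-TR/small-angle steady state with an MT
#' saturation term `delta` (percent units):
#' \deqn{S = A \alpha R1 TR' / (\alpha^2/2 + R1 TR' + \delta/100)}
#' with `TR' = TR/1000` in seconds. This form is the algebraic inverse of
#' the MT-saturation map computation, so a simulate-then-fit round trip is
#' exact in the approximation regime.
#'
#' @param A signal amplitude (a.u., proportional to proton density).
#' @param R1 longitudinal relaxation rate in 1/s.
#' @param alpha flip angle in radians, in `[0, pi)`.
#' @param tr repetition time in ms (> 0).
#' @param delta MT saturation in percent units (>= 0).
#' @return signal in a.u. (numeric, shaped like the broadcast inputs).
#' @export
ernst_signal <- function(A, R1, alpha, tr) {
  if (any(tr <= 0)) stop("ernst_signal: tr must be > 0")
  if (any(alpha < 0 | alpha >= pi)) stop("ernst_signal: alpha outside [0, pi)")
  e1 <- exp(-tr * R1 / 1000)
  A * sin(alpha) * (1 - e1) / (1 - cos(alpha) * e1)
}

#' @rdname ernst_signal
#' @export
mt_flash_signal <- function(A, R1, alpha, tr, delta) {
  if (any(tr <= 0)) stop("mt_flash_signal: tr must be > 0")
  trs <- tr / 1000
  A * alpha * R1 * trs / (alpha^2 / 2 + R1 * trs + delta / 100)
}

#' Exact Ernst-equation inversion (validation oracle)
#'
#' Recovers `R1` and `A` from two noiseless spoiled gradient-echo signals at
#' two flip angles by one-dimensional root finding on the exact Ernst
#' equation. This quantifies the error of the rational small-TR/small-angle
#' approximations used in the map-creation path; it is a validation tool and
#' is never used by [create_maps()].
#'
#' @param s_pd,s_t1 signals (scalars or equal-length vectors) of the
#'   low-angle (PDw) and high-angle (T1w) acquisitions.
#' @param alpha_pd,alpha_t1 local flip angles in radians.
#' @param tr_pd,tr_t1 repetition times in ms.
#' @param interval search interval for R1 in 1/s.
#' @return list with numeric vectors `R1` (1/s) and `A` (a.u.).
#' @export
ernst_invert <- function(s_pd, s_t1, alpha_pd, alpha_t1, tr_pd, tr_t1,
                         interval = c(1e-4, 20)) {
  n <- max(length(s_pd), length(s_t1), length(alpha_pd), length(alpha_t1))
  s_pd <- rep_len(s_pd, n); s_t1 <- rep_len(s_t1, n)
  alpha_pd <- rep_len(alpha_pd, n); alpha_t1 <- rep_len(alpha_t1, n)
  R1 <- A <- rep(NA_real_, n)
  shape <- function(alpha, R1, tr) {
    e1 <- exp(-tr * R1 / 1000)
    sin(alpha) * (1 - e1) / (1 - cos(alpha) * e1)
  }
  for (i in seq_len(n)) {
    if (!is.finite(s_pd[i]) || !is.finite(s_t1[i]) ||
        s_pd[i] <= 0 || s_t1[i] <= 0) next
    # ratio of the two signals depends on R1 only
    f <- function(r1) shape(alpha_t1[i], r1, tr_t1) /
      shape(alpha_pd[i], r1, tr_pd) - s_t1[i] / s_pd[i]
    lo <- f(interval[1]); hi <- f(interval[2])
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) next
    root <- stats::uniroot(f, interval, tol = 1e-14)$root
    R1[i] <- root
    A[i] <- s_pd[i] / shape(alpha_pd[i], root, tr_pd)
  }
  list(R1 = R1, A = A)
}
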