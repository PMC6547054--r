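#' Joint R2* estimation across contrasts (ESTATICS)
#'
#' Fits, per voxel, the log-linear model
#' \deqn{\ln S_c(TE) = \ln S_c(0) - R2^* \cdot TE}
#' by unweighted ordinary least squares with a single R2* decay shared
#' across all contrasts and one TE=0 intercept per contrast. Pooling the
#' echoes of all contrasts into one decay estimate raises the effective
#' number of observations and hence the precision of R2* relative to
#' per-contrast fits.
#'
#' Voxels with any non-positive or non-finite signal among the used echoes
#' are excluded from the fit and marked invalid in the mask (the log is
#' undefined there; no epsilon-clipping is applied inside the fit).
#' Negative R2* estimates are preserved in `r2s_raw` (so residual
#' statistics stay untouched) and clipped to zero only in `r2s`; the number
#' of clipped voxels is reported.
#'
#' @param series_list list of 1--3 [mpm_series] (distinct contrasts), each
#'   with >= 2 echoes, on a common grid.
#' @param te_max optional maximum echo time (ms): echoes with TE above it
#'   are dropped before fitting (default: use all echoes).
#' @return object of class `estatics_fit` with elements:
#'   `r2s` (qvol, 1/s, clipped at 0), `r2s_raw` (unclipped),
#'   `log_intercepts` and `intercepts` (named lists of qvol per contrast;
#'   intercepts in signal units), `resid_rss` (named list of qvol: residual
#'   sum of squares per voxel per contrast, log-domain), `n_echoes` (named
#'   integer vector of echoes used), `mask` (qvol, 1 = valid),
#'   `n_clipped`, `n_invalid`, and `meta` (named list of [acq_metadata]).
#' @export
fit_estatics <- function(series_list, te_max = NULL) {
  if (is_mpm_series(series_list)) series_list <- list(series_list)
  if (length(series_list) < 1L) stop("fit_estatics: no input series")
  contrasts <- vapply(series_list, function(s) s$meta$contrast, character(1))
  if (anyDuplicated(contrasts))
    stop("fit_estatics: duplicate contrasts in input")
  names(series_list) <- contrasts
  grid <- assert_common_grid(series_list)

  # echo selection
  sel <- lapply(series_list, function(s) {
    keep <- if (is.null(te_max)) seq_along(s$meta$echo_times)
    else which(s$meta$echo_times <= te_max)
    if (length(keep) < 2L)
      stop("fit_estatics: contrast ", s$meta$contrast,
           " has fewer than 2 usable echoes; use the single-echo path")
    keep
  })

  nvox <- prod(grid$dim)
  ncon <- length(series_list)
  nobs <- sum(lengths(sel))
  if (nobs < ncon + 1L)
    stop("fit_estatics: not enough observations per voxel")

  # stack signals: rows = echoes (all contrasts), cols = voxels
  Y <- matrix(0, nobs, nvox)
  X <- matrix(0, nobs, ncon + 1L)
  row <- 0L
  for (ci in seq_len(ncon)) {
    s <- series_list[[ci]]
    for (e in sel[[ci]]) {
      row <- row + 1L
      Y[row, ] <- s$volumes[[e]]$data
      X[row, ci] <- 1
      X[row, ncon + 1L] <- -s$meta$echo_times[e]
    }
  }

  valid <- colSums(Y > 0 & is.finite(Y)) == nobs
  beta <- matrix(NA_real_, ncon + 1L, nvox)
  rss_c <- matrix(NA_real_, ncon, nvox)
  if (any(valid)) {
    L <- log(Y[, valid, drop = FALSE])
    xtx <- crossprod(X)
    b <- solve(xtx, crossprod(X, L))
    beta[, valid] <- b
    R <- L - X %*% b
    row <- 0L
    for (ci in seq_len(ncon)) {
      ne <- length(sel[[ci]])
      idx <- row + seq_len(ne)
      rss_c[ci, valid] <- colSums(R[idx, , drop = FALSE]^2)
      row <- row + ne
    }
  }

  tmpl <- series_list[[1]]$volumes[[1]]
  to_vol <- function(v) {
    a <- array(v, grid$dim)
    vol_like(a, tmpl)
  }
  r2s_raw <- beta[ncon + 1L, ] * 1000  # 1/ms -> 1/s
  n_clipped <- sum(r2s_raw < 0, na.rm = TRUE)
  r2s <- pmax(r2s_raw, 0)
  log_int <- intercepts <- rss <- stats::setNames(vector("list", ncon),
                                                  contrasts)
  for (ci in seq_len(ncon)) {
    log_int[[ci]] <- to_vol(beta[ci, ])
    intercepts[[ci]] <- to_vol(exp(beta[ci, ]))
    rss[[ci]] <- to_vol(rss_c[ci, ])
  }
  structure(list(
    r2s = to_vol(r2s), r2s_raw = to_vol(r2s_raw),
    log_intercepts = log_int, intercepts = intercepts,
    resid_rss = rss,
    n_echoes = stats::setNames(lengths(sel), contrasts),
    mask = to_vol(valid * 1),
    n_clipped = n_clipped, n_invalid = sum(!valid),
    meta = lapply(series_list, `[[`, "meta")
  ), class = "estatics_fit")
}

is_estatics_fit <- function(x) inherits(x, "estatics_fit")

#' @export
print.estatics_fit <- function(x, ...) {
  cat("estatics_fit:", paste(names(x$intercepts), collapse = "+"),
      sprintf("(%d invalid, %d clipped voxels)\n", x$n_invalid, x$n_clipped))
  invisible(x)
}

#' Per-contrast exponential R2* fit
#'
#' Simple log-linear OLS decay fit of a single multi-echo contrast; the
#' model (and hence the result) is identical to [fit_estatics()] restricted
#' to that one contrast.
#'
#' @param series an [mpm_series] with >= 2 echoes.
#' @inheritParams fit_estatics
#' @return an `estatics_fit` with one intercept.
#' @export
fit_r2s_single <- function(series, te_max = NULL) {
  fit_estatics(list(series), te_max = te_max)
}

#' Extrapolate a contrast to TE = 0
#'
#' Returns the fitted `S(TE=0)` volume, `exp` of the log-domain intercept.
#' Used downstream to remove the T2* modulation from the PD, R1 and MT
#' inputs.
#'
#' @param series the [mpm_series] whose contrast to extract (or a contrast
#'   label).
#' @param fit an [fit_estatics()] result containing that contrast.
#' @return a [qvol] in signal units; invalid voxels are zero (see
#'   `fit$mask` for validity).
#' @export
extrapolate_te_zero <- function(series, fit) {
  stopifnot(is_estatics_fit(fit))
  ctr <- if (is.character(series)) series else series$meta$contrast
  v <- fit$intercepts[[ctr]]
  if (is.null(v))
    stop("extrapolate_te_zero: contrast ", ctr, " absent from fit")
  v
}
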