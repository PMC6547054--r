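#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis, in mm (the kernel width in voxels follows from the voxel size).
#' `fwhm = 0` returns the input bit-identically.
#'
#' @param vol a [qvol] (or 3-D array, assumed 1 mm isotropic).
#' @param fwhm kernel full width at half maximum in mm, >= 0.
#' @param boundary `"zero"` (zero padding; the default -- in tissue-weighted
#'   use the weight map absorbs the edge effect) or `"replicate"` (edge
#'   value replication).
#' @return smoothed [qvol].
#' @export
gaussian_smooth <- function(vol, fwhm, boundary = c("zero", "replicate")) {
  boundary <- match.arg(boundary)
  if (!is.finite(fwhm) || fwhm < 0)
    stop("gaussian_smooth: fwhm must be >= 0")
  if (!is_qvol(vol)) vol <- qvol(as_vol_array(vol))
  if (fwhm == 0) return(vol)
  d <- vol$data
  for (ax in 1:3) {
    K <- smoothing_matrix(dim(d)[ax], fwhm, vol$voxdim[ax], boundary)
    if (is.null(K)) next
    d <- apply_along_axis(d, ax, K)
  }
  vol_like(d, vol)
}

# 1-D Gaussian convolution as an n x n band matrix with the requested
# boundary handling; NULL for singleton axes (nothing to smooth across)
smoothing_matrix <- function(n, fwhm, voxsize, boundary) {
  if (n < 2L) return(NULL)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxsize  # voxels
  radius <- ceiling(4 * sigma)
  if (radius < 1) radius <- 1
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - radius):(i + radius)
    inside <- j >= 1 & j <= n
    K[i, j[inside]] <- K[i, j[inside]] + k[inside]
    if (boundary == "replicate") {
      K[i, 1] <- K[i, 1] + sum(k[j < 1])
      K[i, n] <- K[i, n] + sum(k[j > n])
    }
  }
  K
}

# multiply band matrix K along axis ax of 3-D array d
apply_along_axis <- function(d, ax, K) {
  dm <- dim(d)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  dp <- aperm(d, perm)
  m <- matrix(dp, dm[ax], prod(dm[-ax]))
  m <- K %*% m
  dim(m) <- dm[perm]
  aperm(m, inv)
}

#' Tissue weight map
#'
#' Nonnegative voxelwise weights (typically modulated warped tissue
#' probabilities from a segmentation) used for tissue-weighted smoothing.
#'
#' @param w [qvol] or array of weights, all finite and >= 0, at least one
#'   positive.
#' @param tissue character label.
#' @return object of class `tissue_weight_map`.
#' @export
tissue_weight_map <- function(w, tissue = "tissue") {
  if (!is_qvol(w)) w <- qvol(as_vol_array(w))
  if (any(w$data < 0)) stop("tissue_weight_map: weights must be >= 0")
  if (!any(w$data > 0)) stop("tissue_weight_map: all weights are zero")
  structure(list(w = w, tissue = tissue), class = "tissue_weight_map")
}

#' Tissue-weighted (VBQ) smoothing
#'
#' Smooths a quantitative map without mixing values across tissue
#' boundaries:
#' \deqn{p = \frac{g \ast (w \, q)}{g \ast w}}
#' where `g` is the Gaussian kernel and `w` the tissue weights. The output
#' is a locally weighted mean of `q`, so boundary voxels are dominated by
#' their own tissue class rather than biased by the neighbour class (which
#' is what plain Gaussian smoothing does to quantitative values). The
#' result is defined only where the smoothed, max-normalised weights exceed
#' `mask_threshold`; elsewhere the output is `NA` with the companion mask
#' set to 0 (zeros are valid quantitative values, so missingness is
#' explicit, never encoded as 0). Normalising the weights by their maximum
#' before thresholding makes the operation exactly invariant to global
#' rescaling of `w`.
#'
#' @param qmap quantitative map ([qvol] or array).
#' @param weights a [tissue_weight_map] (or [qvol]/array of weights).
#' @param fwhm Gaussian kernel FWHM in mm.
#' @param mask_threshold validity threshold in (0, 1) on the smoothed
#'   normalised weights (default 0.05).
#' @inheritParams gaussian_smooth
#' @return list with `map` ([qvol]; `NA` outside the validity mask) and
#'   `mask` ([qvol], 1 = defined).
#' @export
vbq_smooth <- function(qmap, weights, fwhm, mask_threshold = 0.05,
                       boundary = c("zero", "replicate")) {
  boundary <- match.arg(boundary)
  if (!(mask_threshold > 0 && mask_threshold < 1))
    stop("vbq_smooth: mask_threshold must be in (0, 1)")
  if (inherits(weights, "tissue_weight_map")) weights <- weights$w
  if (!is_qvol(qmap)) qmap <- qvol(as_vol_array(qmap))
  w <- as_vol_array(weights)
  if (!identical(dim(w), dim(qmap$data)))
    stop("vbq_smooth: weights not on the map grid")
  w <- w / max(w)
  num <- gaussian_smooth(vol_like(w * qmap$data, qmap), fwhm, boundary)$data
  den <- gaussian_smooth(vol_like(w, qmap), fwhm, boundary)$data
  ok <- den > mask_threshold
  if (!any(ok))
    stop("vbq_smooth: all weights below threshold after smoothing")
  out <- array(NA_real_, dim(w))
  out[ok] <- num[ok] / den[ok]
  map <- vol_like(ifelse(ok, out, NA), qmap)
  # NA is the missing-data sentinel here; qvol() zeroes non-finite values,
  # so restore the sentinel and keep the count in the companion mask
  map$data[!ok] <- NA_real_
  list(map = map, mask = vol_like(ok * 1, qmap))
}

#' @rdname vbq_smooth
#' @param weight_maps list of [tissue_weight_map] (one per tissue class).
#' @return `vbq_smooth_per_tissue()`: named list of `vbq_smooth()` results,
#'   one per tissue class.
#' @export
vbq_smooth_per_tissue <- function(qmap, weight_maps, fwhm,
                                  mask_threshold = 0.05,
                                  boundary = c("zero", "replicate")) {
  if (length(weight_maps) == 0L)
    stop("vbq_smooth_per_tissue: empty weight map list")
  out <- lapply(weight_maps, function(wm)
    vbq_smooth(qmap, wm, fwhm, mask_threshold, boundary))
  nm <- vapply(seq_along(weight_maps), function(i) {
    wm <- weight_maps[[i]]
    if (inherits(wm, "tissue_weight_map")) wm$tissue
    else paste0("class", i)
  }, character(1))
  stats::setNames(out, nm)
}
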