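# Independent oracles and small fixtures used across the suite.
# Oracles are deliberately written with different algorithms than the
# package code paths they check.

# Ernst signal at A = 1000, R1 = 1 /s, TR = 25 ms, alpha = 6 degrees,
# evaluated with arbitrary-precision arithmetic (sympy) and frozen here.
ERNST_REF_A1000_R1_TR25_A6 <- 85.9328840170228277

# brute-force 3-D Gaussian convolution by direct summation over a
# zero-padded array (no separability, no matrix algebra)
oracle_gauss3d <- function(arr, fwhm, voxdim = c(1, 1, 1)) {
  dm <- dim(arr)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxdim
  rad <- pmax(1, ceiling(4 * sig))
  ax <- lapply(1:3, function(a) {
    k <- exp(-(seq(-rad[a], rad[a]))^2 / (2 * sig[a]^2))
    k / sum(k)
  })
  K <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  pad <- array(0, dm + 2 * rad)
  pad[rad[1] + 1:dm[1], rad[2] + 1:dm[2], rad[3] + 1:dm[3]] <- arr
  out <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    win <- pad[i:(i + 2 * rad[1]), j:(j + 2 * rad[2]), k:(k + 2 * rad[3])]
    out[i, j, k] <- sum(K * win)
  }
  out
}

# direct-sum 1-D convolution with a normalised Gaussian, zero padding
oracle_conv1d <- function(x, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- max(1, ceiling(4 * sig))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sig^2))
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - rad):(i + rad)
    ok <- idx >= 1 & idx <= n
    out[i] <- sum(k[ok] * x[idx[ok]])
  }
  out
}

# small noiseless phantom + simulated series, shared by several files
tiny_phantom <- function(dims = c(16, 16, 16), seed = 1, ft_range = 0,
                         fr_range = 0, noise = "none", sigma = 0) {
  make_layered_phantom(dims, seed = seed, ft_range = ft_range,
                       fr_range = fr_range, noise = noise, sigma = sigma)
}

# single-voxel multi-echo series stacked as independent replicates along
# the first array axis (used for Monte-Carlo estimator comparisons)
replicate_series <- function(meta, s0, r2s, sigma, nrep, seed) {
  set.seed(seed)
  vols <- lapply(seq_along(meta$echo_times), function(e) {
    s <- s0 * exp(-meta$echo_times[e] * r2s / 1000)
    qvol(array(s + rnorm(nrep, 0, sigma), c(nrep, 1, 1)))
  })
  mpm_series(meta, vols)
}
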