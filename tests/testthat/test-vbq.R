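test_that("Gaussian smoothing: identity, constants and kernel shape", {
  set.seed(1)
  v <- qvol(array(rnorm(12^3), c(12, 12, 12)))
  # fwhm 0 is bit-identical
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  expect_error(gaussian_smooth(v, -1), "fwhm")

  # constant map unchanged: everywhere under replicate boundary, in the
  # interior under zero padding (the edge decay is the documented default)
  cst <- qvol(array(3.14, c(20, 20, 20)))
  sm_r <- gaussian_smooth(cst, 4, boundary = "replicate")
  expect_equal(sm_r$data, cst$data, tolerance = 1e-12)
  sm_z <- gaussian_smooth(cst, 4, boundary = "zero")
  inner <- sm_z$data[10:11, 10:11, 10:11]
  expect_equal(inner, cst$data[10:11, 10:11, 10:11], tolerance = 1e-12)
  expect_lt(sm_z$data[1, 1, 1], 3.14)

  # delta input reproduces the separable normalised Gaussian kernel
  dlt <- array(0, c(15, 15, 15)); dlt[8, 8, 8] <- 1
  sm <- gaussian_smooth(qvol(dlt), 3)
  sig <- 3 / (2 * sqrt(2 * log(2)))
  rad <- ceiling(4 * sig)
  k1 <- exp(-(seq(-rad, rad))^2 / (2 * sig^2)); k1 <- k1 / sum(k1)
  prof <- sm$data[(8 - rad):(8 + rad), 8, 8] / sm$data[8, 8, 8] * k1[rad + 1]
  expect_equal(prof, k1, tolerance = 1e-6)
  # full 3-D agreement with the brute-force direct-sum oracle
  expect_equal(sm$data, oracle_gauss3d(dlt, 3), tolerance = 1e-12)

  # anisotropic voxels: kernel width follows mm, not voxels
  va <- qvol(dlt, voxdim = c(1, 2, 1))
  sma <- gaussian_smooth(va, 3)
  expect_gt(sma$data[8, 8, 8], sm$data[8, 8, 8])  # narrower in voxel units
})

two_class_1d <- function(n = 40, split = 20) {
  q <- array(c(rep(1, split), rep(2, n - split)), c(n, 1, 1))
  wA <- array(c(rep(1, split), rep(0, n - split)), c(n, 1, 1))
  list(q = qvol(q), wA = qvol(wA), wB = qvol(1 - wA), n = n, split = split)
}

test_that("tissue-weighted smoothing reduces to Gaussian smoothing for w == 1", {
  set.seed(2)
  q <- qvol(array(rnorm(18^3, 5), c(18, 18, 18)))
  w <- qvol(array(1, c(18, 18, 18)))
  vb <- vbq_smooth(q, w, fwhm = 4, mask_threshold = 0.05)
  gs <- gaussian_smooth(q, 4)
  ok <- vb$mask$data > 0
  # within the mask the weight normalisation cancels exactly
  expect_equal(vb$map$data[ok],
               (gs$data / gaussian_smooth(w, 4)$data)[ok], tolerance = 1e-12)
  # and in the deep interior (more than a kernel radius from every edge)
  # it equals plain smoothing
  ctr <- array(FALSE, c(18, 18, 18)); ctr[9:10, 9:10, 9:10] <- TRUE
  expect_equal(vb$map$data[ctr], gs$data[ctr], tolerance = 1e-9)
})

test_that("weighted smoothing of a constant is that constant", {
  f <- two_class_1d()
  qc <- qvol(array(7, c(f$n, 1, 1)))
  vb <- vbq_smooth(qc, f$wA, fwhm = 3, mask_threshold = 0.05)
  ok <- vb$mask$data > 0
  expect_true(any(ok))
  expect_equal(vb$map$data[ok], rep(7, sum(ok)), tolerance = 1e-12)
})

test_that("tissue weighting avoids the boundary bias of plain smoothing", {
  f <- two_class_1d()
  fw <- 3  # voxels (1 mm voxels)
  vb <- vbq_smooth(f$q, f$wA, fwhm = fw, mask_threshold = 0.05)
  gs_pkg <- gaussian_smooth(f$q, fw)
  # brute-force direct-sum oracle for both routes
  gq <- oracle_conv1d(as.vector(f$q$data), fw)
  gwq <- oracle_conv1d(as.vector(f$wA$data * f$q$data), fw)
  gw <- oracle_conv1d(as.vector(f$wA$data), fw)
  expect_equal(as.vector(gs_pkg$data), gq, tolerance = 1e-12)
  ok <- vb$mask$data > 0
  expect_equal(vb$map$data[ok], (gwq / gw)[as.vector(ok)], tolerance = 1e-12)

  # inside class A (q = 1): weighted estimate beats plain smoothing,
  # strictly at boundary-adjacent voxels
  inA <- which(as.vector(f$wA$data) == 1 & as.vector(ok))
  err_vb <- abs(vb$map$data[inA] - 1)
  err_gs <- abs(as.vector(gs_pkg$data)[inA] - 1)
  expect_true(all(err_vb <= err_gs + 1e-12))
  expect_lt(err_vb[f$split], err_gs[f$split])      # adjacent to boundary
  expect_gt(err_gs[f$split], 0.05)

  # weighted-mean bounds: output within class-A value range {1}
  expect_true(all(vb$map$data[ok] >= 1 - 1e-9 & vb$map$data[ok] <= 1 + 1e-9))
})

test_that("weighted smoothing is exactly invariant to weight rescaling", {
  set.seed(3)
  q <- qvol(array(runif(10^3, 1, 2), c(10, 10, 10)))
  w <- array(runif(10^3), c(10, 10, 10))
  a <- vbq_smooth(q, qvol(w), fwhm = 4)
  b <- vbq_smooth(q, qvol(1e4 * w), fwhm = 4)
  expect_identical(a$mask$data, b$mask$data)
  expect_equal(a$map$data, b$map$data, tolerance = 1e-12)

  # bounds property on general weights
  ok <- a$mask$data > 0
  sup <- max(q$data[w > 0]); inf <- min(q$data[w > 0])
  expect_true(all(a$map$data[ok] <= sup + 1e-9))
  expect_true(all(a$map$data[ok] >= inf - 1e-9))
})

test_that("per-tissue smoothing handles classes independently", {
  f <- two_class_1d()
  res <- vbq_smooth_per_tissue(
    f$q, list(tissue_weight_map(f$wA, "A"), tissue_weight_map(f$wB, "B")),
    fwhm = 3)
  expect_named(res, c("A", "B"))
  okA <- res$A$mask$data > 0
  okB <- res$B$mask$data > 0
  expect_equal(res$A$map$data[okA], rep(1, sum(okA)), tolerance = 1e-9)
  expect_equal(res$B$map$data[okB], rep(2, sum(okB)), tolerance = 1e-9)

  # single all-one class reduces to Gaussian smoothing on the mask
  one <- vbq_smooth_per_tissue(f$q, list(tissue_weight_map(
    qvol(array(1, c(f$n, 1, 1))), "all")), fwhm = 3)
  gs <- gaussian_smooth(f$q, 3)
  ok <- one$all$mask$data > 0
  inner <- ok & seq_len(f$n) %in% 10:30
  expect_equal(one$all$map$data[inner], gs$data[inner], tolerance = 1e-9)

  # permuting the class list permutes the outputs
  res2 <- vbq_smooth_per_tissue(
    f$q, list(tissue_weight_map(f$wB, "B"), tissue_weight_map(f$wA, "A")),
    fwhm = 3)
  expect_equal(res2$A$map$data, res$A$map$data)
  expect_error(vbq_smooth_per_tissue(f$q, list(), 3), "empty")
})

test_that("degenerate weight inputs are rejected", {
  q <- qvol(array(1, c(8, 8, 8)))
  expect_error(tissue_weight_map(qvol(array(-1, c(8, 8, 8)))), ">= 0")
  expect_error(tissue_weight_map(qvol(array(0, c(8, 8, 8)))), "zero")
  expect_error(vbq_smooth(q, qvol(array(1, c(8, 8, 8))), 3,
                          mask_threshold = 1.5), "mask_threshold")
})
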