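test_that("joint fit is exact on noiseless shared-decay data", {
  ph <- tiny_phantom(c(12, 12, 12))
  ser <- simulate_mpm(ph)
  fit <- fit_estatics(unname(ser))
  fg <- ph$foreground$data > 0 & fit$mask$data > 0
  expect_true(any(fg))
  expect_equal(fit$r2s$data[fg], ph$R2s$data[fg], tolerance = 1e-9)
  # intercepts equal the noiseless TE=0 signals
  s0 <- ernst_signal(ph$A$data, ph$R1$data, 6 * pi / 180, 25)
  expect_equal(fit$intercepts$PDw$data[fg], s0[fg], tolerance = 1e-9)
  # background voxels (zero signal) are masked invalid, not clipped
  expect_true(all(fit$mask$data[ph$foreground$data == 0] == 0))
})

test_that("constant signal across echoes gives R2* = 0 and that constant intercept", {
  meta <- acq_metadata("PDw", 6, 25, c(2.3, 5, 8, 11))
  vols <- lapply(1:4, function(e) qvol(array(123.4, c(4, 4, 4))))
  fit <- fit_estatics(list(mpm_series(meta, vols)))
  expect_equal(max(abs(fit$r2s$data)), 0, tolerance = 1e-10)
  expect_equal(fit$intercepts$PDw$data[2, 2, 2], 123.4, tolerance = 1e-10)
})

test_that("single-contrast decay fit recovers an exact exponential", {
  meta <- acq_metadata("PDw", 6, 25, seq(2.3, 14.8, length.out = 6))
  vols <- lapply(meta$echo_times, function(te)
    qvol(array(100 * exp(-0.020 * te), c(3, 3, 3))))
  s <- mpm_series(meta, vols)
  fit <- fit_r2s_single(s)
  expect_equal(fit$r2s$data[1, 1, 1], 20, tolerance = 1e-9)
  # identical to the joint fit on one contrast
  fit2 <- fit_estatics(list(s))
  expect_identical(fit$r2s$data, fit2$r2s$data)
})

test_that("noisy fit agrees with a generic least-squares solver", {
  set.seed(11)
  meta_pd <- acq_metadata("PDw", 6, 25, seq(2.3, 14.8, length.out = 6))
  meta_t1 <- acq_metadata("T1w", 21, 25, seq(2.3, 14.8, length.out = 6))
  mk <- function(meta, s0) {
    vols <- lapply(meta$echo_times, function(te)
      qvol(array(s0 * exp(-0.02 * te) * exp(rnorm(1, 0, 0.02)), c(1, 1, 1))))
    mpm_series(meta, vols)
  }
  s_pd <- mk(meta_pd, 90); s_t1 <- mk(meta_t1, 60)
  fit <- fit_estatics(list(s_pd, s_t1))
  # independent route: lm on the stacked log-linear design
  y <- log(c(vapply(s_pd$volumes, function(v) v$data[1], numeric(1)),
             vapply(s_t1$volumes, function(v) v$data[1], numeric(1))))
  X <- cbind(pd = rep(c(1, 0), each = 6), t1 = rep(c(0, 1), each = 6),
             slope = -c(meta_pd$echo_times, meta_t1$echo_times))
  beta <- qr.solve(X, y)
  expect_equal(fit$r2s$data[1, 1, 1], unname(beta["slope"]) * 1000,
               tolerance = 1e-10)
  expect_equal(log(fit$intercepts$PDw$data[1, 1, 1]), unname(beta["pd"]),
               tolerance = 1e-10)
})

test_that("estimator is scale-equivariant and stable under echo removal", {
  ph <- tiny_phantom(c(10, 10, 10))
  ser <- simulate_mpm(ph)
  fit <- fit_estatics(unname(ser))
  fg <- fit$mask$data > 0

  # scaling one contrast shifts only its log intercept, R2* unchanged
  ser2 <- ser
  ser2$T1w$volumes <- lapply(ser2$T1w$volumes, function(v)
    qvol(3.7 * v$data, voxdim = v$voxdim, affine = v$affine))
  fit2 <- fit_estatics(unname(ser2))
  expect_equal(fit2$r2s$data[fg], fit$r2s$data[fg], tolerance = 1e-9)
  expect_equal(fit2$log_intercepts$T1w$data[fg] -
                 fit$log_intercepts$T1w$data[fg],
               rep(log(3.7), sum(fg)), tolerance = 1e-9)
  expect_equal(fit2$log_intercepts$PDw$data[fg],
               fit$log_intercepts$PDw$data[fg], tolerance = 1e-9)

  # dropping the last echo leaves the noiseless estimate unchanged
  drop_last <- function(s) {
    m <- s$meta
    mpm_series(acq_metadata(m$contrast, m$flip_angle, m$tr,
                            m$echo_times[-length(m$echo_times)]),
               s$volumes[-length(s$volumes)])
  }
  fit3 <- fit_estatics(lapply(unname(ser), drop_last))
  expect_equal(fit3$r2s$data[fg], fit$r2s$data[fg], tolerance = 1e-9)
})

test_that("TE=0 extrapolation returns the fitted intercept volume", {
  ph <- tiny_phantom(c(10, 10, 10))
  ser <- simulate_mpm(ph)
  fit <- fit_estatics(unname(ser))
  fg <- fit$mask$data > 0
  ext <- extrapolate_te_zero(ser$MTw, fit)
  s0 <- mt_flash_signal(ph$A$data, ph$R1$data, 6 * pi / 180, 25,
                        ph$delta$data)
  expect_equal(ext$data[fg], s0[fg], tolerance = 1e-9)
  expect_error(extrapolate_te_zero("T2w", fit), "absent")
})

test_that("noisy extrapolation matches a nonlinear curve fit within its SE", {
  set.seed(42)
  te <- seq(2.3, 14.8, length.out = 6)
  meta <- acq_metadata("PDw", 6, 25, te)
  strue <- 100 * exp(-0.02 * te)
  y <- strue + rnorm(6, 0, 1)
  fit <- fit_r2s_single(mpm_series(meta, lapply(y, function(v)
    qvol(array(v, c(1, 1, 1))))))
  nl <- stats::nls(y ~ a * exp(-b * te), start = list(a = 100, b = 0.02))
  a_hat <- coef(nl)[["a"]]
  a_se <- summary(nl)$coefficients["a", "Std. Error"]
  expect_lt(abs(fit$intercepts$PDw$data[1] - a_hat), a_se)
})

test_that("single-echo input is rejected with a pointer to the single-echo path", {
  meta <- acq_metadata("PDw", 6, 25, 2.3)
  s <- mpm_series(meta, list(qvol(array(1, c(4, 4, 4)))))
  expect_error(fit_estatics(list(s)), "single-echo")
})
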