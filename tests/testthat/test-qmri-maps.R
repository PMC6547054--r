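# Exact Ernst-inversion oracle: per-compartment check that the rational
# approximations are within their documented envelope, and that the exact
# inverter itself recovers truth (so the envelope measurement is trusted).
test_that("dual-angle R1/A recover truth within the approximation envelope", {
  co <- default_compartments()
  a_pd <- 6 * pi / 180; a_t1 <- 21 * pi / 180
  for (k in seq_len(nrow(co))) {
    s_pd <- ernst_signal(co$A[k], co$R1[k], a_pd, 25)
    s_t1 <- ernst_signal(co$A[k], co$R1[k], a_t1, 25)
    ex <- ernst_invert(s_pd, s_t1, a_pd, a_t1, 25, 25)
    expect_equal(ex$R1, co$R1[k], tolerance = 1e-7)
    expect_equal(ex$A, co$A[k], tolerance = 1e-7)

    r1 <- compute_r1(array(s_pd, c(2, 2, 2)), array(s_t1, c(2, 2, 2)),
                     acq_metadata("PDw", 6, 25, 2.3),
                     acq_metadata("T1w", 21, 25, 2.3))
    amp <- compute_amplitude(array(s_pd, c(2, 2, 2)), array(s_t1, c(2, 2, 2)),
                             acq_metadata("PDw", 6, 25, 2.3),
                             acq_metadata("T1w", 21, 25, 2.3))
    expect_lt(abs(r1$map$data[1] - co$R1[k]) / co$R1[k], 0.015)
    expect_lt(abs(amp$map$data[1] - co$A[k]) / co$A[k], 0.015)
  }
})

test_that("R1 formula: unity transmit field is the identity, inputs are symmetric", {
  s_pd <- array(80, c(3, 3, 3)); s_t1 <- array(60, c(3, 3, 3))
  m_pd <- acq_metadata("PDw", 6, 25, 2.3)
  m_t1 <- acq_metadata("T1w", 21, 25, 2.3)
  r_null <- compute_r1(s_pd, s_t1, m_pd, m_t1)
  r_one <- compute_r1(s_pd, s_t1, m_pd, m_t1, ft = array(1, c(3, 3, 3)))
  expect_equal(r_null$map$data, r_one$map$data)
  r_swap <- compute_r1(s_t1, s_pd, m_t1, m_pd)
  expect_equal(r_swap$map$data, r_null$map$data, tolerance = 1e-12)
  expect_error(compute_r1(s_pd, s_t1, m_pd,
                          acq_metadata("T1w", 6, 25, 2.3)), "degenerate")
})

test_that("amplitude is homogeneous of degree one in the intercepts", {
  s_pd <- array(80, c(2, 2, 2)); s_t1 <- array(60, c(2, 2, 2))
  m_pd <- acq_metadata("PDw", 6, 25, 2.3)
  m_t1 <- acq_metadata("T1w", 21, 25, 2.3)
  a1 <- compute_amplitude(s_pd, s_t1, m_pd, m_t1)
  a2 <- compute_amplitude(2 * s_pd, 2 * s_t1, m_pd, m_t1)
  expect_equal(a2$map$data, 2 * a1$map$data, tolerance = 1e-12)
})

test_that("MT saturation inverts its forward model exactly", {
  m_mt <- acq_metadata("MTw", 6, 25, 2.3)
  alpha <- 6 * pi / 180
  A <- array(1000, c(3, 3, 3)); R1 <- array(1.05, c(3, 3, 3))
  # no MT effect: small-angle steady state, delta must come back 0
  s0 <- mt_flash_signal(A, R1, alpha, 25, 0)
  d0 <- compute_mt_sat(s0, A, R1, m_mt)
  expect_equal(max(abs(d0$map$data)), 0, tolerance = 1e-9)
  # delta = 2 p.u. round trip
  s2 <- mt_flash_signal(A, R1, alpha, 25, 2)
  d2 <- compute_mt_sat(s2, A, R1, m_mt)
  expect_equal(d2$map$data, array(2, c(3, 3, 3)), tolerance = 1e-6)
  # non-positive signal masked
  s2[1, 1, 1] <- 0
  dm <- compute_mt_sat(s2, A, R1, m_mt)
  expect_equal(dm$mask$data[1, 1, 1], 0)
})

test_that("empirical MT B1 correction reduces residual transmit dependence", {
  m_mt <- acq_metadata("MTw", 6, 25, 2.3)
  alpha_nom <- 6 * pi / 180
  A <- 1000; R1 <- 1.05; d_true <- 2
  fts <- seq(0.8, 1.2, by = 0.05)
  # forward-simulate at the true local angle, invert assuming nominal
  d_app <- vapply(fts, function(ft) {
    s <- mt_flash_signal(A, R1, ft * alpha_nom, 25, d_true)
    compute_mt_sat(array(s, c(1, 1, 1)), array(A, c(1, 1, 1)),
                   array(R1, c(1, 1, 1)), m_mt)$map$data[1]
  }, numeric(1))
  d_corr <- vapply(seq_along(fts), function(i)
    b1_correct_mt(array(d_app[i], c(1, 1, 1)),
                  ft = array(fts[i], c(1, 1, 1)))$map$data[1], numeric(1))
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(d_corr), cv(d_app))

  # identities
  d <- array(2, c(2, 2, 2))
  expect_equal(b1_correct_mt(d, ft = array(1, c(2, 2, 2)))$map$data, d)
  expect_equal(b1_correct_mt(d, ft = array(1.2, c(2, 2, 2)), C = 0)$map$data, d)
  expect_error(b1_correct_mt(d, ft = NULL, C = 1.2), "C must be")
})

test_that("spoiling correction defaults to disabled and honours identities", {
  r1 <- array(c(0.7, 1.05), c(2, 1, 1))
  off <- apply_spoiling_correction(r1)
  expect_false(off$enabled)
  expect_equal(off$map$data, r1)

  ident <- spoiling_coefficients(0, 1)
  on <- apply_spoiling_correction(r1, ft = array(1, c(2, 1, 1)),
                                  coeffs = ident)
  expect_true(on$enabled)
  expect_equal(on$map$data, r1, tolerance = 1e-12)

  # linear coefficients with Acoef(1) = 0, Bcoef(1) = 1 reduce to identity
  lin <- spoiling_coefficients(c(5, -5), c(0.8, 0.2))
  at1 <- apply_spoiling_correction(r1, ft = array(1, c(2, 1, 1)), coeffs = lin)
  expect_equal(at1$map$data, r1, tolerance = 1e-12)
  # and change the map away from ft = 1
  at08 <- apply_spoiling_correction(r1, ft = array(0.8, c(2, 1, 1)),
                                    coeffs = lin)
  expect_false(isTRUE(all.equal(at08$map$data, r1)))
})

test_that("PD calibration hits its target, is scale invariant, preserves ratios", {
  a <- array(c(rep(0.8, 10), rep(1.0, 10), rep(0, 7)), c(27, 1, 1))
  mask <- a > 0
  cal <- calibrate_pd(a, mask = mask, target = 100)
  expect_equal(mean(cal$map$data[mask]), 100, tolerance = 1e-9)
  cal2 <- calibrate_pd(5 * a, mask = mask, target = 100)
  expect_equal(cal2$map$data, cal$map$data, tolerance = 1e-12)
  # two-compartment ratio preserved exactly under the global scaling
  v <- cal$map$data
  expect_equal(mean(v[1:10]) / mean(v[11:20]), 0.8, tolerance = 1e-12)
  expect_error(calibrate_pd(a, mask = a > 2), "empty")
  # default without mask: relative calibration to mean 100
  rel <- calibrate_pd(a)
  expect_false(rel$calibrated)
  expect_equal(mean(rel$map$data[a > 0]), 100, tolerance = 1e-9)
})
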