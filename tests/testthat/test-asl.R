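test_that("saturation-recovery model matches the discrete Bloch oracle", {
  p <- look_locker_protocol()
  for (r1 in c(0.3, 0.8, 1.5, 3.0)) {
    model <- model_saturation_recovery(r1, 100, p, seq_len(16))
    oracle <- bloch_ll_oracle(r1, 100, p)
    expect_equal(model, oracle, tolerance = 1e-10)
  }
  # slice-timing-corrected saturation delay enters the first-pulse term
  p5 <- look_locker_protocol(slice_index = 5)
  expect_equal(model_saturation_recovery(1.2, 50, p5, 5),
               bloch_ll_oracle(1.2, 50, p5)[5], tolerance = 1e-10)
})

test_that("saturation-recovery model has the right limits", {
  p <- look_locker_protocol()
  a <- pi / 6
  expect_equal(model_saturation_recovery(1, 100, p, 1),
               100 * sin(a) * (1 - exp(-0.05)), tolerance = 1e-12)
  # geometric-series steady state at large pulse index
  p_long <- look_locker_protocol(n_phases = 400)
  e <- exp(-0.52 * 1)
  expect_equal(model_saturation_recovery(1, 100, p_long, 400),
               100 * sin(a) * (1 - e) / (1 - cos(a) * e), tolerance = 1e-8)
  expect_error(model_saturation_recovery(-0.1, 100, p, 1), "positive")
})

test_that("R1 fitting recovers noiseless series and is init-insensitive", {
  ser <- gen_look_locker(1.0, 100, noise_sd = 0)
  fit <- fit_saturation_recovery(ser)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$r1, 1.0), 1e-6)
  expect_lt(rel_err(fit$s0, 100), 1e-6)

  # basin check: a 5x5 grid of admissible inits reaches the same optimum
  inits <- expand.grid(r1 = seq(0.2, 3, length.out = 5),
                       s0 = c(20, 60, 100, 150, 300))
  r1s <- apply(inits, 1, function(p)
    fit_saturation_recovery(ser, init = c(p[1], p[2]))$r1)
  expect_lt(max(abs(r1s - 1.0)), 1e-5)

  expect_error(fit_saturation_recovery(
    ll_series(rep(0, 16), look_locker_protocol())), "degenerate")
})

test_that("R1 fitting is unbiased at 1 percent noise", {
  biases <- vapply(seq_len(500), function(k) {
    ser <- gen_look_locker(1.0, 100, noise_sd = 1, seed = 1000 + k)
    fit_saturation_recovery(ser)$r1 - 1.0
  }, numeric(1))
  expect_lt(abs(median(biases)), 0.01)
})

test_that("background-suppression factor matches the bookkeeping oracle", {
  p <- pcasl_protocol()
  for (r1 in c(0.2, 0.5, 0.77, 1.2, 2.5)) {
    expect_equal(bs_recovery_factor(r1, p), bloch_bs_oracle(r1, p),
                 tolerance = 1e-12)
  }
  for (i in c(0L, 7L, 15L)) {
    expect_equal(bs_recovery_factor(0.77, p, i), bloch_bs_oracle(0.77, p, i),
                 tolerance = 1e-12)
  }
  # readout delay of slice 0 is exactly the base delay
  expect_equal(readout_td(p, 0), 3.6)
  expect_equal(readout_td(p, 15), 3.6 + 0.032 * 15)
})

test_that("recovery factor lies in (0, 1] with the stated limits", {
  p <- pcasl_protocol()
  d <- bs_recovery_factor(10^seq(-3, 2, length.out = 200), p)
  expect_true(all(d > 0 & d <= 1))
  expect_equal(bs_recovery_factor(100, p), 1, tolerance = 1e-12)
  expect_lt(bs_recovery_factor(1e-4, p), 1e-3)
})

test_that("M0 calibration divides the early controls by the recovery factor", {
  s <- gen_pcasl(rep(60, 4), rep(1000, 4), r1_tissue = 0.77, noise_sd = 0)
  cal <- compute_m0(s)
  expect_equal(cal$m0, rep(1000, 4), tolerance = 1e-8)
  expect_equal(cal$r1, rep(0.77, 4), tolerance = 1e-6)
  # at very fast relaxation the factor is 1 and M0 is the raw control mean
  r1_fast <- rep(100, 4)
  cal_fast <- compute_m0(s, r1 = r1_fast)
  expect_equal(cal_fast$m0, rowMeans(s$control[, 1:6]), tolerance = 1e-12)
})

test_that("haemoglobin conversion and blood T1 behave as configured", {
  # constant override makes T1 independent of haemoglobin
  expect_equal(blood_t1_from_hgb(6, c1 = 0, c0 = 1 / 1.65)$t1_blood, 1.65)
  expect_equal(blood_t1_from_hgb(11, c1 = 0, c0 = 1 / 1.65)$t1_blood, 1.65)
  # group-mean haemoglobin of 9.1 mmol/l maps to haematocrit near 0.44
  expect_equal(blood_t1_from_hgb(9.1)$hct, 0.44, tolerance = 0.005)
  # T1 strictly decreasing in haemoglobin for positive slope
  t1s <- vapply(seq(5, 12, by = 0.5),
                function(h) blood_t1_from_hgb(h)$t1_blood, numeric(1))
  expect_true(all(diff(t1s) < 0))
  expect_warning(blood_t1_from_hgb(3), "plausibility")
})

test_that("CBF quantification inverts the kinetic model", {
  blood <- blood_properties(9.1, 0.44, 1.65)
  s <- gen_pcasl(rep(60, 4), rep(1000, 4), blood = blood, noise_sd = 0)
  cal <- compute_m0(s)
  cbf <- quantify_cbf(s, cal$m0, blood)
  expect_equal(cbf$cbf, rep(60, 4), tolerance = 1e-8)

  # zero difference signal quantifies to zero flow
  s0 <- gen_pcasl(rep(0, 4), rep(1000, 4), blood = blood, noise_sd = 0)
  cbf0 <- quantify_cbf(s0, compute_m0(s0)$m0, blood)
  expect_equal(cbf0$cbf, rep(0, 4))

  # scaling difference signal and M0 together leaves CBF unchanged
  s2 <- s
  s2$control <- 3 * s$control; s2$label <- 3 * s$label
  s2$calibration <- 3 * s$calibration
  cal2 <- compute_m0(s2)
  expect_equal(quantify_cbf(s2, cal2$m0, blood)$cbf, cbf$cbf,
               tolerance = 1e-8)
})

test_that("grey-matter mean respects the partial-volume threshold", {
  blood <- blood_properties(9.1, 0.44, 1.65)
  s <- gen_pcasl(c(rep(60, 5), rep(20, 5)), rep(1000, 10), blood = blood,
                 noise_sd = 0)
  cbf <- quantify_cbf(s, compute_m0(s)$m0, blood)
  gm <- c(rep(0.95, 5), rep(0.3, 5))
  expect_equal(gm_mean_cbf(cbf, gm, threshold = 0.8), 60, tolerance = 1e-8)
  expect_equal(gm_mean_cbf(cbf, rep(1, 10), threshold = 0.8), 40,
               tolerance = 1e-8)
  expect_error(gm_mean_cbf(cbf, rep(0.1, 10)), "empty")
})

test_that("grey-matter CBF recovery is accurate at 2 percent image noise", {
  blood <- blood_properties(9.1, 0.44, 1.65)
  # noise at 2 percent of the background-suppressed control amplitude
  ctrl_level <- 1000 * bs_recovery_factor(0.77, pcasl_protocol())
  est <- vapply(seq_len(100), function(k) {
    s <- gen_pcasl(rep(60, 12), rep(1000, 12), blood = blood,
                   noise_sd = 0.02 * ctrl_level, seed = 5000 + k)
    cal <- compute_m0(s)
    gm_mean_cbf(quantify_cbf(s, cal$m0, blood), rep(1, 12))
  }, numeric(1))
  expect_lt(abs(mean(est) - 60) / 60, 0.02)
  expect_lt(sd(est) / 60, 0.05)
})
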