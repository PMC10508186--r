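test_that("every generator is bit-identical under a fixed seed", {
  p <- look_locker_protocol()
  expect_identical(gen_look_locker(1.0, 100, p, noise_sd = 2, seed = 7),
                   gen_look_locker(1.0, 100, p, noise_sd = 2, seed = 7))
  expect_false(identical(gen_look_locker(1, 100, p, 2, seed = 7)$samples,
                         gen_look_locker(1, 100, p, 2, seed = 8)$samples))

  expect_identical(gen_pcasl(rep(60, 3), rep(1000, 3), noise_sd = 5, seed = 3),
                   gen_pcasl(rep(60, 3), rep(1000, 3), noise_sd = 5, seed = 3))

  vs <- vessel_spec(c(0, 0), 4, 30)
  expect_identical(gen_pcm_phantom(vs, noise_sd = 0.05, seed = 5),
                   gen_pcm_phantom(vs, noise_sd = 0.05, seed = 5))

  expect_identical(gen_sbo_phantom(0.7, 0.44, noise_sd = 0.01, seed = 2),
                   gen_sbo_phantom(0.7, 0.44, noise_sd = 0.01, seed = 2))

  expect_identical(
    gen_spectrum(c(naa = 10, lactate = 0.5), noise_sd = 0.02, seed = 9),
    gen_spectrum(c(naa = 10, lactate = 0.5), noise_sd = 0.02, seed = 9))

  d <- repeated_design(10, c("baseline", "6h"), 100, 8, 3)
  expect_identical(gen_repeated_physiology(d, seed = 4),
                   gen_repeated_physiology(d, seed = 4))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(gen_look_locker(1, 100, noise_sd = 1, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("added noise has the requested standard deviation", {
  clean <- gen_spectrum(c(naa = 10, lactate = 0.5), noise_sd = 0,
                        n_points = 16384)
  noisy <- gen_spectrum(c(naa = 10, lactate = 0.5), noise_sd = 0.05,
                        n_points = 16384, seed = 11)
  expect_lt(rel_err(sd(noisy$real - clean$real), 0.05), 0.05)
})

test_that("look-locker phantom matches the forward model and Bloch oracle", {
  p <- look_locker_protocol()
  # single-pulse saturation recovery collapses to S0 sin(a) (1 - exp(-TD R1))
  s1 <- gen_look_locker(1.0, 100, p, noise_sd = 0)$samples[1]
  expect_equal(s1, 100 * sin(pi / 6) * (1 - exp(-0.05 * 1.0)),
               tolerance = 1e-12)
  expect_length(gen_look_locker(1, 100, p)$samples, 16)
  ser <- gen_look_locker(0.8, 100, p, noise_sd = 0)
  expect_equal(ser$samples, bloch_ll_oracle(0.8, 100, p), tolerance = 1e-10)
  expect_error(gen_look_locker(-1, 100, p), "positive")
  expect_error(gen_look_locker(1, 0, p), "positive")
})

test_that("pCASL phantom has zero difference signal at zero perfusion", {
  s <- gen_pcasl(rep(0, 4), rep(1000, 4), noise_sd = 0)
  expect_equal(max(abs(s$control - s$label)), 0)
  expect_error(gen_pcasl(rep(60, 3), rep(1000, 4)), "shape")
})

test_that("PCM phantom conserves per-pixel flow and wraps aliased phase", {
  vs <- vessel_spec(c(0, 0), 5, 10, "uniform")
  ph <- gen_pcm_phantom(vs, venc = 100, noise_sd = 0)
  m <- ph$masks[[1]]
  # conservation: ground truth equals the pixel sum exactly
  expect_equal(ph$ground_truth$flow_ml_min,
               sum(ph$velocity_true[m]) * ph$pixel_area_cm2 * 60,
               tolerance = 1e-10)
  # uniform disc: flow = v * area
  expect_equal(ph$ground_truth$flow_ml_min,
               10 * sum(m) * ph$pixel_area_cm2 * 60, tolerance = 1e-12)

  # velocity above venc wraps: 120 cm/s at venc 100 is stored as -80 cm/s
  wrapped <- gen_pcm_phantom(vessel_spec(c(0, 0), 5, 120), venc = 100,
                             noise_sd = 0)
  in_phase <- wrapped$phase[wrapped$masks[[1]]]
  expect_equal(unique(round(in_phase / pi * 100, 9)), -80)

  expect_error(gen_pcm_phantom(list(vessel_spec(c(0, 0), 5, 10),
                                    vessel_spec(c(3, 0), 5, 10))),
               "overlap")
})

test_that("parabolic vessel mean velocity matches the integration oracle", {
  vs <- vessel_spec(c(0, 0), 6, 80, "parabolic")
  grid <- phantom_grid(96, 0.5)
  ph <- gen_pcm_phantom(vs, grid = grid, noise_sd = 0)
  m <- ph$masks[[1]]
  # independent pixel-centre integration of the Poiseuille profile
  r2 <- (grid$x - 0)^2 + (grid$y - 0)^2
  oracle_mean <- mean(80 * (1 - r2[m] / 36))
  expect_equal(ph$ground_truth$mean_velocity, oracle_mean, tolerance = 1e-12)
  # analytic disc mean of a parabola is half the peak, up to rim pixels
  expect_lt(rel_err(oracle_mean, 40), 0.03)
})

test_that("SBO phantom phase scales with echo time and deoxygenation", {
  # fully oxygenated blood leaves no vessel-tissue phase difference
  ph <- gen_sbo_phantom(1.0, 0.44, noise_sd = 0)
  expect_equal(max(abs(ph$pair$phase_echo1)), 0)
  expect_equal(max(abs(ph$pair$phase_echo2)), 0)
  # orthogonal vessel: the two echoes have phase ratio te2/te1
  ph <- gen_sbo_phantom(0.7, 0.44, theta = 0, noise_sd = 0)
  s <- ph$sinus_mask
  expect_equal(mean(ph$pair$phase_echo2[s]) / mean(ph$pair$phase_echo1[s]),
               0.01783 / 0.00816, tolerance = 1e-12)
  expect_error(gen_sbo_phantom(0.7, 0.44, theta = acos(sqrt(1 / 3))),
               "magic angle")
})

test_that("spectrum phantom emits the stated lines and windows", {
  sp <- gen_spectrum(c(naa = 0, lactate = 0.5), noise_sd = 0)
  w <- sp$ppm >= 1.9 & sp$ppm <= 2.1
  f <- sp$ppm * sp$hz_per_ppm
  area_naa <- sum(diff(f[w]) * (sp$real[w][-1] + sp$real[w][-sum(w)]) / 2)
  expect_lt(abs(area_naa), 5e-3)  # only far Lorentzian tails remain
  expect_equal(sp$te, 0.288)
  expect_error(gen_spectrum(c(naa = 10, lactate = 0.5), linewidth = -1),
               "positive")
  expect_error(gen_spectrum(c(naa = 10, lactate = 0.5),
                            tissue_fractions = c(0.5, 0.4, 0.3)), "sum")
})

test_that("repeated-physiology cells follow the two-level noise model", {
  d0 <- repeated_design(5, c("baseline", "6h", "1d"), 80, 0, 0)
  rm0 <- gen_repeated_physiology(d0)
  expect_true(all(rm0$values == 80))

  d <- repeated_design(10000, c("baseline", "6h"), 100, 8, 3)
  rm <- gen_repeated_physiology(d, seed = 21)
  expect_lt(rel_err(var(rm$values[, "baseline"]), 8^2 + 3^2), 0.02)

  ga <- repeated_design(10, c("baseline", "6h", "1d", "7d"), 57.5, 8, 3)
  expect_equal(dim(gen_repeated_physiology(ga)$values), c(10L, 4L))
})
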