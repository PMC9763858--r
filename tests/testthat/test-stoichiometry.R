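cfg <- patch_config()

test_that("Chung-Kennedy filter preserves constants and noiseless steps", {
  expect_equal(chung_kennedy_filter(rep(100, 30), 5, 2), rep(100, 30))
  tr <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 0)$trace
  filt <- chung_kennedy_filter(tr, 5, 2)
  # plateaus exact, transition confined to at most one sample at the edge
  expect_equal(filt[1:49], rep(200, 49))
  expect_equal(filt[52:100], rep(100, 49))
  expect_true(all(filt[50:51] >= 100 & filt[50:51] <= 200))
  expect_error(chung_kennedy_filter(rep(1, 10), W = 5), "length")
})

test_that("noisy steps are located within two samples in most runs", {
  hits <- vapply(1:200, function(s) {
    tr <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 30, seed = s)
    st <- detect_steps(chung_kennedy_filter(tr$trace, 5, 2), 50, 5)
    nrow(st) >= 1 && any(abs(st$position - 50) <= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("step detection recovers sizes and counts", {
  tr <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 0)$trace
  st <- detect_steps(chung_kennedy_filter(tr, 5, 2), 50, 5)
  expect_equal(nrow(st), 1)
  expect_lte(abs(st$position - 50), 1)
  expect_equal(st$size, 100, tolerance = 1e-9)
  # noiseless 4-molecule cascade: modal step size = I_1
  tr4 <- simulate_intensity_trace(c(400, 300, 200, 100), 30, noise_sd = 0)$trace
  st4 <- detect_steps(chung_kennedy_filter(tr4, 5, 2), 50, 5)
  expect_equal(nrow(st4), 3)
  expect_equal(st4$size, rep(100, 3), tolerance = 1e-9)
  # two noisy steps found in >= 90% of runs
  hits <- vapply(1:200, function(s) {
    tr <- simulate_intensity_trace(c(300, 200, 100), 40, noise_sd = 20, seed = s)
    nrow(detect_steps(chung_kennedy_filter(tr$trace, 5, 2), 50, 5)) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # upward-only changes are not steps
  up <- simulate_intensity_trace(c(100, 200), 40, noise_sd = 0)$trace
  expect_equal(nrow(detect_steps(chung_kennedy_filter(up, 5, 2), 50, 5)), 0)
})

test_that("initial intensity extrapolation equals closed-form least squares", {
  expect_equal(initial_track_intensity(rep(100, 5), 0:4, 5, 0), 100)
  # slope -10 through frames 1..5 evaluated at 0 -> 110
  expect_equal(initial_track_intensity(c(100, 90, 80, 70, 60), 1:5, 5, 0), 110)
  # exponential-decay points: agree with the independent OLS oracle to 1e-9
  y <- 500 * exp(-(2:6) / 12)
  expect_equal(initial_track_intensity(y, 2:6, 5, 0),
               ols_oracle(2:6, y, 0), tolerance = 1e-9)
  # rising early intensities fall back to the mean
  expect_equal(initial_track_intensity(c(100, 120, 140), 0:2, 5, 0), 120)
  expect_true(is.na(initial_track_intensity(100, 0, 5, 0)))
})

test_that("stoichiometry gating and scaling are exact", {
  linked <- data.frame(track_id = rep(c(1, 2), each = 5),
                       frame = c(0:4, 30:34),
                       I = c(rep(200, 5), rep(300, 5)))
  st <- track_stoichiometry(linked, 100, cfg, t0_frame = 0)
  expect_equal(st$S[st$track_id == 1], 2)
  expect_true(st$included[st$track_id == 1])
  expect_false(st$included[st$track_id == 2])   # starts at frame 30 > gate
  expect_error(track_stoichiometry(linked, -5, cfg), "positive")
  # scale equivariance: multiplying intensities and I_1 by c leaves S fixed
  st2 <- track_stoichiometry(transform(linked, I = I * 7.5), 750, cfg)
  expect_equal(st2$S, st$S, tolerance = 1e-12)
})

test_that("calibration recovers the unitary brightness", {
  sim <- simulate_assembly_stack(n_assemblies = 20,
                                 stoichiometries = rep(2:6, 4),
                                 p_bleach = 0.02, dim_hw = c(160, 160),
                                 n_frames = 250, seed = 205)
  foci <- detect_foci(sim$stack, cfg)
  linked <- link_foci(foci, cfg)
  c1 <- single_fluorophore_brightness(sim$stack, foci, linked,
                                      "modal_postbleach", cfg)
  expect_lt(abs(c1$i1 - 100) / 100, 0.1)
  expect_gte(c1$support, 10)
  c2 <- single_fluorophore_brightness(sim$stack, foci, linked,
                                      "step_intervals", cfg, i1_hint = c1$i1)
  expect_lt(abs(c2$i1 - 100) / 100, 0.15)
  expect_lt(abs(c2$i1 - c1$i1) / c1$i1, 0.15)
  # stack that never bleaches is a calibration error
  sim0 <- simulate_assembly_stack(n_assemblies = 5, p_bleach = 0,
                                  dim_hw = c(96, 96), n_frames = 30, seed = 6)
  f0 <- detect_foci(sim0$stack, cfg)
  expect_error(single_fluorophore_brightness(sim0$stack, f0, NULL,
                                             "modal_postbleach", cfg),
               "calibration error")
})

test_that("stoichiometry KDE is a unit-mass fixed-kernel estimate", {
  k1 <- stoichiometry_kde(5, bw = 0.6)
  expect_equal(k1$x[which.max(k1$y)], 5, tolerance = 0.05)
  expect_equal(max(k1$y), stats::dnorm(0, sd = 0.6), tolerance = 1e-3)
  k4 <- stoichiometry_kde(c(2, 4, 6, 8), bw = 0.6)
  pk <- k4$x[which(diff(sign(diff(k4$y))) == -2) + 1]
  expect_equal(pk, c(2, 4, 6, 8), tolerance = 0.1)
  # integrates to one (trapezoid over the grid)
  area <- sum(diff(k4$x) * (head(k4$y, -1) + tail(k4$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_error(stoichiometry_kde(numeric(0)), "no stoichiometry")
})

test_that("periodicity recovers exact and noisy dimer spacings", {
  p <- periodicity(c(2, 4, 6, 8, 10), bw = 0.6)
  expect_equal(p$interval, 2, tolerance = 0.05)
  expect_error(periodicity(c(1, 2)), "at least 3")
  # raw-interval method on the same sparse set also sees spacing 2
  p2 <- periodicity(c(2, 4, 6, 8, 10), bw = 0.6, method = "raw_intervals")
  expect_equal(p2$interval, 2, tolerance = 0.05)
  expect_equal(p2$intervals, rep(2, 4))
  # dimer lattice with measurement noise: peak in [1.7, 2.3]
  set.seed(17)
  s <- 2 * sample(1:20, 200, replace = TRUE) + rnorm(200, 0, 0.3)
  p3 <- periodicity(s, bw = 0.6)
  expect_gte(p3$interval, 1.7)
  expect_lte(p3$interval, 2.3)
  # error formula: bw * sqrt(mean(S)/n_extrap) / n_under_peak
  expect_equal(p3$error,
               0.6 * sqrt(mean(s) / 5) / p3$n_under_peak, tolerance = 1e-12)
  expect_equal(p3$error_alt,
               0.6 * sqrt(mean(s) / (5 * p3$n_under_peak)), tolerance = 1e-12)
})
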