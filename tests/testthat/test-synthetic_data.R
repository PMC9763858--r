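test_that("noiseless stacks carry exactly stoichiometry x unitary brightness", {
  sim <- simulate_assembly_stack(stoichiometries = c(1L, 3L, 7L),
                                 positions_px = cbind(c(30, 70, 50), c(30, 30, 70)),
                                 i1 = 100, p_bleach = 0, bg = 2, noise = FALSE,
                                 dim_hw = c(100, 100), n_frames = 3, seed = 1)
  for (t in 1:3) {
    fr <- sim$stack$frames[, , t]
    expect_equal(sum(fr) - 100 * 100 * 2, (1 + 3 + 7) * 100, tolerance = 1e-3)
  }
  # per-spot integrated intensity is N * I_1 (windowed sum around each spot)
  fr <- sim$stack$frames[, , 1] - 2
  for (a in 1:3) {
    rows <- (sim$truth$y_px[a] - 10):(sim$truth$y_px[a] + 10)
    cols <- (sim$truth$x_px[a] - 10):(sim$truth$x_px[a] + 10)
    expect_equal(sum(fr[round(rows) + 1, round(cols) + 1]),
                 sim$truth$stoichiometry[a] * 100, tolerance = 0.1)
  }
})

test_that("photobleaching survival is geometric with the requested rate", {
  p <- 0.05
  sim <- simulate_assembly_stack(stoichiometries = rep(50L, 10), p_bleach = p,
                                 dim_hw = c(128, 128), n_frames = 1, seed = 3)
  bf <- unlist(sim$bleach_frames)
  expect_length(bf, 500)
  expect_equal(mean(bf), 1 / p, tolerance = 3 * (sqrt((1 - p)) / p) / sqrt(500) / (1 / p))
  expect_true(all(bf >= 1))
  # expected total intensity is non-increasing in time
  sim2 <- simulate_assembly_stack(n_assemblies = 10, p_bleach = 0.1, noise = FALSE,
                                  dim_hw = c(96, 96), n_frames = 30, seed = 4)
  totals <- apply(sim2$stack$frames, 3, sum)
  expect_true(all(diff(totals) <= 1e-9))
})

test_that("assembly stacks are reproducible and bounded by the frame", {
  s1 <- simulate_assembly_stack(n_assemblies = 5, dim_hw = c(64, 64),
                                n_frames = 4, seed = 9)
  s2 <- simulate_assembly_stack(n_assemblies = 5, dim_hw = c(64, 64),
                                n_frames = 4, seed = 9)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth, s2$truth)
  expect_error(simulate_assembly_stack(positions_px = matrix(c(200, 10), 1),
                                       stoichiometries = 1L,
                                       dim_hw = c(64, 64), n_frames = 1),
               "inside the frame")
  expect_error(simulate_assembly_stack(n_assemblies = 2, bg = -1,
                                       dim_hw = c(64, 64), n_frames = 1),
               "non-negative")
  expect_warning(simulate_assembly_stack(n_assemblies = 2, psf_sigma_nm = 10,
                                         dim_hw = c(64, 64), n_frames = 1,
                                         seed = 1),
                 "undersampled")
})

test_that("CSR pattern counts follow the Poisson mean lambda * area", {
  # 100 um^2 at lambda = 2 -> mean 200; average over many seeds
  counts <- vapply(1:300, function(s)
    nrow(simulate_point_pattern("csr", c(10000, 10000), lambda_per_um2 = 2,
                                seed = s)$pattern$points), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 200), 2 * se + 1e-9)
})

test_that("lattice patterns honour spacing and jitter conventions", {
  exact <- simulate_point_pattern("lattice_jitter", c(2000, 2000),
                                  spacing_nm = 500, jitter_rms_nm = 0, seed = 1)
  pts <- exact$pattern$points
  expect_equal(nrow(pts), 16)
  expect_true(all(pts[, 1] %in% c(250, 750, 1250, 1750)))
  # rms jitter defaults to half the spacing (per-axis sd a / (2 sqrt 2))
  jit <- simulate_point_pattern("lattice_jitter", c(40000, 40000),
                                spacing_nm = 500, seed = 2)
  expect_equal(jit$truth$jitter_rms_nm, 250)
  same <- simulate_point_pattern("lattice_jitter", c(40000, 40000),
                                 spacing_nm = 500, seed = 2)
  expect_identical(jit$pattern$points, same$pattern$points)
  expect_error(simulate_point_pattern("csr", lambda_per_um2 = -2), "positive")
  expect_error(simulate_point_pattern("lattice_jitter", spacing_nm = 0),
               "positive")
})

test_that("all simulated points lie inside their region", {
  for (kind in c("csr", "lattice_jitter", "clustered")) {
    p <- simulate_point_pattern(kind, c(8000, 6000), seed = 5)$pattern
    expect_true(all(p$points[, 1] >= 0 & p$points[, 1] <= 8000))
    expect_true(all(p$points[, 2] >= 0 & p$points[, 2] <= 6000))
  }
})

test_that("intensity traces reproduce their schedule and seed", {
  tr <- simulate_intensity_trace(c(100), 50, noise_sd = 0)
  expect_identical(tr$trace, rep(100, 50))
  tr2 <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 0)
  expect_identical(tr2$trace, c(rep(200, 50), rep(100, 50)))
  expect_identical(tr2$truth$change_points, 50)
  a <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 10, seed = 3)
  b <- simulate_intensity_trace(c(200, 100), 50, noise_sd = 10, seed = 3)
  expect_identical(a$trace, b$trace)
  expect_error(simulate_intensity_trace(numeric(0)), "nonempty")
  expect_error(simulate_intensity_trace(100, 10, noise_sd = -1), "non-negative")
})
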