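cfg <- patch_config()
sig <- psf_sigma_px(cfg)

test_that("constant frames contain no candidates", {
  expect_equal(nrow(detect_candidates(matrix(5, 64, 64))), 0)
  expect_error(detect_candidates(matrix(1, 10, 10)), "smaller")
})

test_that("candidates sit on isolated spots and are deduplicated", {
  fr <- spot_frame(rbind(c(30, 40)), 500, dim_hw = c(64, 64), bg = 1)
  cand <- detect_candidates(fr, 8, 17)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$x_px - 30) + abs(cand$y_px - 40), 2)
  # two spots 20 px apart -> two candidates
  fr2 <- spot_frame(rbind(c(20, 30), c(40, 30)), c(500, 400),
                    dim_hw = c(64, 64), bg = 1)
  expect_equal(nrow(detect_candidates(fr2, 8, 17)), 2)
  # two spots 5 px apart (inside one detection disk) -> the brighter wins
  fr3 <- spot_frame(rbind(c(30, 30), c(35, 30)), c(500, 300),
                    dim_hw = c(64, 64), bg = 1)
  cand3 <- detect_candidates(fr3, 8, 17)
  expect_equal(nrow(cand3), 1)
  expect_lt(abs(cand3$x_px - 30), 2.5)
})

test_that("Gaussian-mask centroids are exact on symmetric noiseless spots", {
  fr <- spot_frame(rbind(c(30, 40)), 300, dim_hw = c(64, 64), bg = 0)
  f <- gaussian_mask_fit(fr, c(30, 40), sigma_px = sig)
  expect_true(f$converged)
  expect_equal(f$x_px, 30, tolerance = 1e-6)
  expect_equal(f$y_px, 40, tolerance = 1e-6)
  expect_equal(f$I, 300, tolerance = 300 * 1e-3)
  # all-zero frame with a forced seed: nothing to fit
  z <- gaussian_mask_fit(matrix(0, 64, 64), c(30, 40), sigma_px = sig)
  expect_true(z$rejected)
  expect_equal(z$I, 0)
  expect_equal(z$snr, 0)
})

test_that("sub-pixel localization matches a least-squares Gaussian oracle", {
  set.seed(21)
  for (k in 1:6) {
    x0 <- 25 + runif(1); y0 <- 33 + runif(1)
    fr <- spot_frame(rbind(c(x0, y0)), 400, dim_hw = c(64, 64), bg = 0)
    f <- gaussian_mask_fit(fr, round(c(x0, y0)), sigma_px = sig)
    expect_lt(abs(f$x_px - x0), 0.05)
    expect_lt(abs(f$y_px - y0), 0.05)
    oracle <- gauss_lsq_oracle(fr, round(c(x0, y0)), sig)
    expect_lt(abs(f$x_px - oracle[1]), 0.05)
    expect_lt(abs(f$y_px - oracle[2]), 0.05)
  }
})

test_that("fitted intensity is linear in molecule count on noiseless spots", {
  sim <- simulate_assembly_stack(stoichiometries = c(1L, 2L, 4L, 8L, 16L),
                                 positions_px = cbind(c(20, 60, 100, 20, 60),
                                                      c(20, 20, 20, 60, 60)),
                                 i1 = 100, p_bleach = 0, bg = 2, noise = FALSE,
                                 dim_hw = c(128, 128), n_frames = 1, seed = 2)
  foci <- detect_foci(sim$stack, cfg)
  m <- match_foci(foci, sim$truth)
  expect_false(anyNA(m))
  rel <- foci$I / (sim$truth$stoichiometry[m] * 100)
  expect_true(all(abs(rel - 1) < 0.01))
})

test_that("localization precision at high SNR is well below the pixel size", {
  # integrated SNR ~ 10 spots: rms error of matched detections ~< 40 nm
  i10 <- 10 * sqrt(1.25) * sqrt(sum(outer((-8:8)^2, (-8:8)^2, "+") <= 36))
  sim <- simulate_assembly_stack(n_assemblies = 10,
                                 stoichiometries = rep(1L, 10), i1 = i10,
                                 p_bleach = 0, dim_hw = c(128, 128),
                                 n_frames = 12, min_sep_px = 10, seed = 31)
  foci <- detect_foci(sim$stack, cfg)
  m <- match_foci(foci, sim$truth)
  err_nm <- sqrt((foci$x_px - sim$truth$x_px[m])^2 +
                 (foci$y_px - sim$truth$y_px[m])^2)[!is.na(m)] * 53
  expect_gt(sum(!is.na(m)), 80)
  expect_lt(sqrt(mean(err_nm^2)), 40)
})

test_that("SNR filtering preserves order and acts as a pure threshold", {
  foci <- data.frame(frame = 1:5, snr = c(5, 1, 3, 0.5, 8))
  expect_equal(filter_by_snr(foci, 0), foci)
  kept <- filter_by_snr(foci, 3)
  expect_equal(kept$frame, c(1, 3, 5))
  expect_error(filter_by_snr(foci, -1))
})

test_that("detection recall and false-positive rate meet the operating point", {
  # recall >= 90% for spots at SNR 5 (peak signal / background noise sd),
  # separated by >= 2 PSF FWHM
  i5 <- 5 * 2 * pi * sig^2 * sqrt(1.25)
  det <- 0; tot <- 0
  for (s in 1:10) {
    sim <- simulate_assembly_stack(n_assemblies = 12,
                                   stoichiometries = rep(1L, 12), i1 = i5,
                                   p_bleach = 0, dim_hw = c(128, 128),
                                   n_frames = 1, min_sep_px = 10,
                                   seed = 500 + s)
    foci <- detect_foci(sim$stack, cfg)
    for (a in 1:12) {
      d2 <- (foci$x_px - sim$truth$x_px[a])^2 +
            (foci$y_px - sim$truth$y_px[a])^2
      det <- det + any(d2 < 4); tot <- tot + 1
    }
  }
  expect_gte(det / tot, 0.9)
  # <= 1 false positive per 100 blank frames at the default threshold
  set.seed(123)
  nfp <- 0
  for (i in 1:100) {
    st <- image_stack(blank_frame(), 53)
    nfp <- nfp + nrow(detect_foci(st, cfg))
  }
  expect_lte(nfp, 1)
})
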