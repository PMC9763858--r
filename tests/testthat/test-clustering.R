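cfg <- patch_config()

test_that("photobleach correction recovers exponential decay", {
  means <- 100 * exp(-(0:9) / 7)
  st <- image_stack(array(rep(means, each = 32 * 32), c(32, 32, 10)), 100)
  bc <- bleach_correct_zstack(st, means)
  expect_equal(bc$tau_frames, 7, tolerance = 1e-6)
  corrected <- apply(bc$stack$frames, 3, mean)
  expect_true(all(abs(corrected - 100) / 100 < 0.01))
  # noisy decay: tau recovered within 5%
  set.seed(8)
  noisy <- 100 * exp(-(0:19) / 12) * (1 + rnorm(20, 0, 0.02))
  bc2 <- bleach_correct_zstack(st, noisy)
  expect_lt(abs(bc2$tau_frames - 12) / 12, 0.05)
  # flat reference: identity; brightening reference: error
  bc3 <- bleach_correct_zstack(st, rep(50, 10))
  expect_equal(bc3$stack$frames, st$frames)
  expect_error(bleach_correct_zstack(st, c(1, 2, 4, 8)), "no admissible")
})

test_that("Otsu threshold matches the exhaustive between-class oracle", {
  img <- matrix(50, 40, 40); img[10:14, 10:14] <- 200
  thr <- otsu_threshold(img)
  expect_identical(unname(img > thr), unname(img == 200))
  set.seed(30)
  for (k in 1:5) {
    v <- c(rnorm(400, 60, 12), rnorm(120, 180, 25))
    v <- pmin(pmax(round(v), 0), 255)
    expect_equal(otsu_threshold(v), otsu_oracle(v), tolerance = 1e-9)
  }
  expect_error(otsu_threshold(matrix(3, 5, 5)), "segmentation error")
})

test_that("binarization isolates puncta and drops sub-minimum objects", {
  img <- matrix(50, 60, 60)
  img[10:13, 10:13] <- 200      # 16 px object
  img[40, 40] <- 200            # single-pixel speckle
  mask <- binarize_puncta(img, local_radius = 25, min_size = 4)
  expect_true(all(mask[10:13, 10:13]))
  expect_false(mask[40, 40])
  expect_equal(sum(mask), 16)
  expect_error(binarize_puncta(matrix(1, 60, 60)), "segmentation error")
})

test_that("synthetic puncta fields segment into one object per punctum", {
  set.seed(2)
  px <- 53; H <- 192; W <- 192
  pts <- simulate_point_pattern("csr", c(W * px, H * px),
                                lambda_per_um2 = 1.5, seed = 8)$pattern
  pp <- pts$points / px
  pp <- pp[pp[, 1] > 8 & pp[, 1] < W - 9 & pp[, 2] > 8 & pp[, 2] < H - 9, ,
           drop = FALSE]
  # keep only puncta resolvable by any segmentation: prune pairs closer
  # than two PSF FWHM (same resolvability convention as focus detection)
  dmat <- as.matrix(dist(pp)); diag(dmat) <- Inf
  keep <- rep(TRUE, nrow(pp))
  for (i in seq_len(nrow(pp))) {
    if (!keep[i]) next
    close_j <- which(dmat[i, ] < 2 * 2.3548 * 90 / px & keep)
    keep[close_j[close_j > i]] <- FALSE
  }
  pp <- pp[keep, , drop = FALSE]
  sig <- 90 / px
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(pp))) {
    cols <- round(pp[i, 1]) + (-6:6); rows <- round(pp[i, 2]) + (-6:6)
    fx <- pnorm((cols + 0.5 - pp[i, 1]) / sig) - pnorm((cols - 0.5 - pp[i, 1]) / sig)
    fy <- pnorm((rows + 0.5 - pp[i, 2]) / sig) - pnorm((rows - 0.5 - pp[i, 2]) / sig)
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + 800 * outer(fy, fx)
  }
  img <- matrix(rpois(H * W, img + 5), H, W)
  mask <- binarize_puncta(img, 25, 4)
  obj <- analyze_objects(mask, img, px)
  hits <- vapply(seq_len(nrow(pp)), function(i) {
    d2 <- (obj$x_px - pp[i, 1])^2 + (obj$y_px - pp[i, 2])^2
    sum(d2 < 9)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.9)
})

test_that("object properties follow geometry and connectivity conventions", {
  sq <- matrix(0, 20, 20); sq[8:12, 8:12] <- 1
  o <- analyze_objects(sq == 1)
  expect_equal(o$area_px, 25)
  expect_equal(c(o$x_px, o$y_px), c(9, 9))   # 0-based center of cols/rows 8:12
  dm <- matrix(0, 60, 60)
  dm[outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 20^2] <- 1
  od <- analyze_objects(dm == 1)
  expect_gte(od$circularity, 0.9)
  expect_lte(od$circularity, 1.1)
  # diagonal contact merges under 8-connectivity
  dd <- matrix(0, 12, 12); dd[2:4, 2:4] <- 1; dd[5:7, 5:7] <- 1
  expect_equal(nrow(analyze_objects(dd == 1)), 1)
  expect_equal(nrow(analyze_objects(matrix(FALSE, 5, 5))), 0)
  # intensity-weighted centroid shifts toward the bright side
  img <- matrix(0, 10, 10); img[4:6, 4:6] <- 1; img[4:6, 6] <- 10
  ow <- analyze_objects(img > 0, img)
  expect_gt(ow$x_px, 4)
})

test_that("density maps integrate to the point count with correct scale", {
  one <- density_map(matrix(c(1000, 1000), 1), bw_nm = 180)
  expect_equal(sum(one$z) * (one$grid_step_nm / 1e3)^2, 1, tolerance = 0.01)
  peak_at <- c(one$x_nm[which.max(apply(one$z, 2, max))],
               one$y_nm[which.max(apply(one$z, 1, max))])
  expect_equal(peak_at, c(1000, 1000), tolerance = one$grid_step_nm)
  pat <- simulate_point_pattern("csr", c(20000, 20000), lambda_per_um2 = 2,
                                seed = 12)$pattern
  dm <- density_map(pat)
  expect_equal(sum(dm$z) * (dm$grid_step_nm / 1e3)^2, nrow(pat$points),
               tolerance = 0.01 * nrow(pat$points))
  # spatial mean over the region approximates the true intensity
  inside <- dm$x_nm >= 1000 & dm$x_nm <= 19000
  insidey <- dm$y_nm >= 1000 & dm$y_nm <= 19000
  expect_equal(mean(dm$z[insidey, inside]), 2, tolerance = 0.4)
})

test_that("uncorrected Ripley curves equal the brute-force double loop", {
  pat <- simulate_point_pattern("csr", c(5000, 5000), lambda_per_um2 = 1,
                                seed = 5)$pattern
  expect_gte(nrow(pat$points), 10)
  r <- seq(0, 1200, by = 20)
  rc <- ripley_h(pat, r_nm = r, correction = "none")
  Kb <- ripley_oracle(pat$points, pat$area_um2 * 1e6, r)
  expect_equal(rc$K_um2 * 1e6, Kb, tolerance = 1e-12)
  expect_equal(rc$L_um, sqrt(rc$K_um2 / pi), tolerance = 1e-12)
  expect_equal(rc$H_um, rc$L_um - rc$r_um, tolerance = 1e-12)
  expect_true(all(diff(rc$K_um2) >= 0))
  # below the smallest pair distance, H(r) = -r exactly
  dmin <- min(dist(pat$points))
  early <- r > 0 & r < dmin
  expect_equal(rc$H_um[early], -r[early] / 1e3, tolerance = 1e-12)
  expect_error(ripley_h(point_pattern(cbind(1:5 * 100, 1:5 * 100),
                                      list(type = "rect", w_nm = 5000,
                                           h_nm = 5000))),
               "at least 10")
  expect_warning(ripley_h(pat, r_nm = seq(0, 4000, 20), correction = "none"),
                 "truncated")
})

test_that("CSR is calibrated and structured patterns deviate as expected", {
  pat <- simulate_point_pattern("csr", c(10000, 10000), lambda_per_um2 = 5,
                                seed = 2)$pattern
  rc <- ripley_h(pat, r_nm = seq(0, 2000, 20), correction = "isotropic")
  env <- csr_envelope(nrow(pat$points), pat$roi, seq(0, 2000, 20),
                      nsim = 99, correction = "isotropic", seed = 3)
  inside <- rc$H_um >= env$lo_um & rc$H_um <= env$hi_um
  expect_gte(mean(inside), 0.95)
  # Thomas process: H above the CSR envelope near the cluster scale
  th <- simulate_point_pattern("clustered", c(10000, 10000), seed = 4)$pattern
  rt <- ripley_h(th, r_nm = seq(0, 2000, 20), correction = "isotropic")
  envt <- csr_envelope(nrow(th$points), th$roi, seq(0, 2000, 20),
                       nsim = 99, correction = "isotropic", seed = 5)
  band <- rt$r_um >= 0.2 & rt$r_um <= 0.6
  expect_true(all(rt$H_um[band] > envt$hi_um[band]))
  # jittered lattice: negative H in the dispersion trough
  lat <- simulate_point_pattern("lattice_jitter", c(10000, 10000),
                                spacing_nm = 500, seed = 3)$pattern
  rl <- ripley_h(lat, r_nm = seq(0, 1000, 20), correction = "isotropic")
  trough <- rl$r_um >= 0.1 & rl$r_um <= 0.35
  expect_true(all(rl$H_um[trough] < 0))
})

test_that("clustering gradient is the KDE mode of adjacent-point gradients", {
  r <- seq(0, 2, by = 0.02)
  lin <- data.frame(r_um = r, K_um2 = pi * (0.004 * r + r)^2,
                    L_um = 0.004 * r + r, H_um = 0.004 * r)
  class(lin) <- c("ripley_curve", "data.frame")
  g <- clustering_gradient(lin)
  expect_lt(abs(g$modal_gradient - 0.004), 1e-4)
  flat <- transform(lin, H_um = 0)
  class(flat) <- c("ripley_curve", "data.frame")
  expect_lt(abs(clustering_gradient(flat)$modal_gradient), 1e-5)
})

test_that("nearest-neighbour distance tracks the initial H minimum", {
  lat <- simulate_point_pattern("lattice_jitter", c(10000, 10000),
                                spacing_nm = 500, seed = 3)$pattern
  rl <- ripley_h(lat, r_nm = seq(0, 1500, 20), correction = "isotropic")
  rnn <- nearest_neighbor_distance(rl)
  dmat <- as.matrix(dist(lat$points)); diag(dmat) <- Inf
  direct <- mean(apply(dmat, 1, min))
  expect_lt(abs(rnn - direct) / direct, 0.3)
  # far-separated points: H = -r up to the pair distance, minimum at the
  # last negative grid point before it
  pts <- cbind(seq(500, 9500, length.out = 10), rep(c(1000, 9000), 5))
  pp <- point_pattern(pts, list(type = "rect", w_nm = 10000, h_nm = 10000))
  rc <- ripley_h(pp, r_nm = seq(0, 1500, 20), correction = "none")
  dmin <- min(dist(pts))
  expect_equal(nearest_neighbor_distance(rc), 20 * floor((dmin - 1e-9) / 20),
               tolerance = 21)
  # scale covariance: rescaling coordinates rescales r_nn, gradient fixed
  lat2 <- point_pattern(lat$points * 2,
                        list(type = "rect", w_nm = 20000, h_nm = 20000))
  rl2 <- ripley_h(lat2, r_nm = seq(0, 3000, 40), correction = "isotropic")
  expect_equal(nearest_neighbor_distance(rl2), 2 * rnn, tolerance = 45)
})

test_that("isotropic correction agrees with an independent Ripley implementation", {
  pat <- simulate_point_pattern("csr", c(10000, 10000), lambda_per_um2 = 3,
                                seed = 9)$pattern
  spatial::ppregion(0, 10, 0, 10)
  pts <- list(x = pat$points[, 1] / 1e3, y = pat$points[, 2] / 1e3,
              area = c(0, 10, 0, 10))
  k <- spatial::Kfn(pts, fs = 2, k = 100)
  rc <- ripley_h(pat, r_nm = k$x * 1000, correction = "isotropic")
  expect_lt(max(abs(rc$L_um - k$y)), 1e-3)
})
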