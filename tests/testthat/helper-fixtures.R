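# Shared fixtures and independent oracles.

psf_sigma_px <- function(cfg = patch_config())
  cfg$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / cfg$pixel_size_nm

# blank camera frame under the default noise model
blank_frame <- function(dim_hw = c(64, 64), bg = 1, read_sd = 0.5) {
  matrix(pmax(0, round(stats::rpois(prod(dim_hw), bg) +
                       stats::rnorm(prod(dim_hw), 0, read_sd))),
         dim_hw[1], dim_hw[2])
}

# single noiseless frame with spots at given positions / intensities
spot_frame <- function(positions_px, intensities, dim_hw = c(64, 64),
                       bg = 0, sigma_px = psf_sigma_px()) {
  sim <- simulate_assembly_stack(
    stoichiometries = rep(1L, nrow(positions_px)),
    positions_px = positions_px,
    i1 = 1, p_bleach = 0, bg = bg, noise = FALSE,
    dim_hw = dim_hw, n_frames = 1,
    psf_sigma_nm = sigma_px * 53, pixel_size_nm = 53, seed = 1L)
  fr <- sim$stack$frames[, , 1] - bg
  out <- matrix(bg, dim_hw[1], dim_hw[2])
  # scale each unit spot: re-render per spot for exact intensities
  for (i in seq_len(nrow(positions_px))) {
    s1 <- simulate_assembly_stack(
      stoichiometries = 1L, positions_px = positions_px[i, , drop = FALSE],
      i1 = intensities[i], p_bleach = 0, bg = 0, noise = FALSE,
      dim_hw = dim_hw, n_frames = 1,
      psf_sigma_nm = sigma_px * 53, pixel_size_nm = 53, seed = 1L)
    out <- out + s1$stack$frames[, , 1]
  }
  out
}

# brute-force nonlinear least-squares 2D Gaussian fit (independent oracle
# for the Gaussian-mask centroid)
gauss_lsq_oracle <- function(frame, guess_xy, sigma_px, half = 8) {
  cx0 <- round(guess_xy[1]); cy0 <- round(guess_xy[2])
  cols <- (cx0 - half):(cx0 + half)
  rows <- (cy0 - half):(cy0 + half)
  win <- frame[rows + 1, cols + 1]
  X <- matrix(rep(cols, each = length(rows)), nrow = length(rows))
  Y <- matrix(rep(rows, times = length(cols)), nrow = length(rows))
  obj <- function(p) {
    mod <- p[3] * exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * sigma_px^2)) + p[4]
    sum((win - mod)^2)
  }
  fit <- stats::optim(c(guess_xy, max(win), min(win)), obj,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  fit$par[1:2]
}

# closed-form OLS of y on x evaluated at x0 (independent oracle for the
# initial-intensity extrapolation)
ols_oracle <- function(x, y, x0) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  a + b * x0
}

# brute-force exhaustive Otsu: maximise between-class variance over all
# candidate thresholds by direct two-class computation
otsu_oracle <- function(v, n_levels = 256) {
  lo <- min(v); hi <- max(v)
  bins <- pmin(floor((v - lo) / (hi - lo) * n_levels), n_levels - 1)
  centers <- lo + (0:(n_levels - 1) + 0.5) * (hi - lo) / n_levels
  vals <- centers[bins + 1]
  best <- -Inf; best_k <- NA
  for (k in 0:(n_levels - 2)) {
    thr <- lo + (k + 1) * (hi - lo) / n_levels
    g0 <- vals[vals <= thr + 1e-12]; g1 <- vals[vals > thr + 1e-12]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(vals)
    bcv <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  lo + (best_k + 1) * (hi - lo) / n_levels
}

# brute-force Ripley K (no correction): double loop over ordered pairs
ripley_oracle <- function(pts, area_nm2, r_nm) {
  n <- nrow(pts)
  sapply(r_nm, function(rr) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= rr) s <- s + 1
    }
    area_nm2 / n^2 * s
  })
}

# match detected foci to true positions within tol_px; returns index of
# matched truth row (NA = false positive)
match_foci <- function(foci, truth, tol_px = 2) {
  vapply(seq_len(nrow(foci)), function(i) {
    d2 <- (truth$x_px - foci$x_px[i])^2 + (truth$y_px - foci$y_px[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol_px^2) j else NA_integer_
  }, integer(1))
}
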