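# Box-filtered local sums with edge-truncated windows, via integral images.
# Returns list(sum, sum2, n) of window sums of m and m^2 and window sizes.
box_stats <- function(m, half) {
  h <- nrow(m); w <- ncol(m)
  win <- function(x) {
    cs <- rbind(0, apply(x, 2, cumsum))
    r1 <- pmax(seq_len(h) - half, 1L); r2 <- pmin(seq_len(h) + half, h)
    sr <- cs[r2 + 1L, , drop = FALSE] - cs[r1, , drop = FALSE]
    cs2 <- cbind(0, t(apply(sr, 1, cumsum)))
    c1 <- pmax(seq_len(w) - half, 1L); c2 <- pmin(seq_len(w) + half, w)
    cs2[, c2 + 1L, drop = FALSE] - cs2[, c1, drop = FALSE]
  }
  nrow_w <- pmin(seq_len(h) + half, h) - pmax(seq_len(h) - half, 1L) + 1L
  ncol_w <- pmin(seq_len(w) + half, w) - pmax(seq_len(w) - half, 1L) + 1L
  list(sum = win(m), sum2 = win(m * m), n = outer(nrow_w, ncol_w))
}

# Relative (dy, dx) offsets of the pixels of a disk of given radius,
# excluding the center.
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2 & !(g$dy == 0 & g$dx == 0), ]
  g
}

#' Detect candidate foci in one frame
#'
#' A candidate is a pixel that is the strict maximum within its disk of
#' radius `radius` pixels and exceeds the mean of its local square
#' background window by at least `min_sd` local standard deviations
#' (`min_sd = 0` is the bare above-local-mean rule; the default
#' configuration uses a positive pre-gate to skip hopeless fits, with
#' final acceptance decided downstream by the SNR threshold).
#' Candidates within one
#' detection radius of a brighter candidate are dropped (tie: smaller
#' (y, x) wins). Candidates are restricted to the margin where the full
#' background window is available, and returned sorted by decreasing peak
#' value.
#'
#' @param frame numeric matrix (one image frame, counts).
#' @param radius detection disk radius (px).
#' @param bg_box local background window side (px, odd).
#' @param min_sd candidate pre-gate in local-noise sd units.
#' @return data.frame with 0-based integer pixel coordinates `x_px`,
#'   `y_px`, the `peak` value and local `bg_mean`, `bg_sd`.
#' @export
detect_candidates <- function(frame, radius = 8, bg_box = 17, min_sd = 0) {
  h <- nrow(frame); w <- ncol(frame)
  if (h < bg_box || w < bg_box)
    stop("frame smaller than the background window")
  half <- (bg_box - 1L) / 2L
  bs <- box_stats(frame, half)
  mu <- bs$sum / bs$n
  va <- pmax(bs$sum2 / bs$n - mu^2, 0) * bs$n / pmax(bs$n - 1, 1)
  sd_loc <- sqrt(va)

  margin <- max(ceiling(radius), half)
  ok <- matrix(FALSE, h, w)
  ok[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  ok <- ok & (frame > mu + min_sd * sd_loc)
  idx <- which(ok)
  if (length(idx) > 0) {
    # strict 3x3 maximum pre-filter, then the full disk
    for (s in c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)) {
      idx <- idx[frame[idx] > frame[idx + s]]
      if (length(idx) == 0) break
    }
  }
  if (length(idx) > 0) {
    offs <- disk_offsets(radius)
    shifts <- as.integer(offs$dy + offs$dx * h)
    shifts <- setdiff(shifts, c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L))
    for (s in shifts) {
      idx <- idx[frame[idx] > frame[idx + s]]
      if (length(idx) == 0) break
    }
  }
  if (length(idx) == 0)
    return(data.frame(x_px = integer(0), y_px = integer(0), peak = numeric(0),
                      bg_mean = numeric(0), bg_sd = numeric(0)))
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  cand <- data.frame(x_px = col - 1L, y_px = row - 1L, peak = frame[idx],
                     bg_mean = mu[idx], bg_sd = sd_loc[idx])
  cand <- cand[order(-cand$peak, cand$y_px, cand$x_px), , drop = FALSE]
  # de-duplicate: keep the brighter of any pair closer than the radius
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand) - 1)) {
      if (!keep[i]) next
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x_px[j] - cand$x_px[i])^2 + (cand$y_px[j] - cand$y_px[i])^2
      keep[j][d2 < radius^2] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Sub-pixel localization by iterative Gaussian masking
#'
#' Refines a candidate to a super-resolved centroid: at each iteration the
#' centroid is updated to the Gaussian-weighted mean of the
#' background-subtracted pixel positions in the fit window, with the
#' Gaussian mask (fixed sd = the PSF sigma) re-centred on the current
#' centroid, until the update falls below `tol` pixels. The local
#' background level and noise are estimated once per focus, from the
#' square annulus of side `bg_annulus` around the seed excluding the
#' detection disk, with one 3-sigma clipping pass to reject pixels lit by
#' neighbouring spots. The integrated intensity is the sum of
#' background-subtracted pixels inside the integration disk (radius
#' `int_radius`, covering > 99.9 % of the point-spread mass) around the
#' final centroid, and `snr = I / (bg_sd * sqrt(n_disk))` with `n_disk`
#' the integration-disk pixel count.
#'
#' @param frame numeric matrix.
#' @param seed_xy numeric length-2, 0-based (x, y) start position; the full
#'   fit window must lie inside the frame.
#' @param radius detection disk radius (px).
#' @param bg_box fit window side (px, odd).
#' @param sigma_px Gaussian mask sd (px).
#' @param tol convergence tolerance (px).
#' @param max_iter maximum iterations; non-convergence flags the focus.
#' @param int_radius integration disk radius (px).
#' @param bg_annulus background annulus outer side (px, odd); truncated at
#'   the frame edge.
#' @return one-row data.frame: `x_px`, `y_px` (sub-pixel, 0-based), `I`,
#'   `bg`, `sigma_px`, `snr`, `converged`, `rejected`.
#' @export
gaussian_mask_fit <- function(frame, seed_xy, radius = 8, bg_box = 17,
                              sigma_px = 180 / (2 * sqrt(2 * log(2))) / 53,
                              tol = 0.01, max_iter = 50,
                              int_radius = 6, bg_annulus = 25) {
  v <- gmask_fit_core(frame, seed_xy, radius, bg_box, sigma_px, tol, max_iter,
                      int_radius, bg_annulus)
  data.frame(x_px = v[1], y_px = v[2], I = v[3], bg = v[4],
             sigma_px = v[5], snr = v[6],
             converged = v[7] == 1, rejected = v[8] == 1)
}

# numeric-vector core of the Gaussian-mask fit:
# c(x, y, I, bg, sigma, snr, converged, rejected)
gmask_fit_core <- function(frame, seed_xy, radius, bg_box, sigma_px,
                           tol, max_iter, int_radius = 6, bg_annulus = 25) {
  h <- nrow(frame); w <- ncol(frame)
  half <- (bg_box - 1L) / 2L
  cx0 <- round(seed_xy[1]); cy0 <- round(seed_xy[2])
  if (cx0 - half < 0 || cx0 + half > w - 1 || cy0 - half < 0 || cy0 + half > h - 1)
    stop("fit window extends outside the frame")

  # local background from the annulus (clipped at frame edges), one
  # sigma-clipping pass against neighbouring spots
  ahalf <- (bg_annulus - 1L) / 2L
  acols <- max(0, cx0 - ahalf):min(w - 1, cx0 + ahalf)
  arows <- max(0, cy0 - ahalf):min(h - 1, cy0 + ahalf)
  awin <- frame[arows + 1L, acols + 1L]
  ad2 <- outer((arows - cy0)^2, (acols - cx0)^2, "+")
  ann <- awin[ad2 > radius^2]
  for (pass in 1:4) {
    m1 <- mean(ann); s1 <- stats::sd(ann)
    if (!is.finite(s1) || s1 <= 0) break
    keep <- ann <= m1 + 3 * s1
    if (all(keep)) break
    ann <- ann[keep]
  }
  bg <- mean(ann)
  bg_sd <- stats::sd(ann)
  if (!is.finite(bg_sd)) bg_sd <- 0

  cols <- (cx0 - half):(cx0 + half)          # 0-based x
  rows <- (cy0 - half):(cy0 + half)          # 0-based y
  win <- frame[rows + 1L, cols + 1L] - bg
  X <- matrix(rep(cols, each = length(rows)), nrow = length(rows))
  Y <- matrix(rep(rows, times = length(cols)), nrow = length(rows))

  cx <- seed_xy[1]; cy <- seed_xy[2]
  converged <- FALSE; rejected <- FALSE
  inv2s2 <- 1 / (2 * sigma_px^2)
  for (k in seq_len(max_iter)) {
    d2 <- (X - cx)^2 + (Y - cy)^2
    wi <- exp(-d2 * inv2s2) * win
    s <- sum(wi)
    if (!is.finite(s) || s <= 0) { rejected <- TRUE; break }
    nx <- sum(wi * X) / s
    ny <- sum(wi * Y) / s
    step <- sqrt((nx - cx)^2 + (ny - cy)^2)
    cx <- nx; cy <- ny
    if (cx < cols[1] || cx > cols[length(cols)] ||
        cy < rows[1] || cy > rows[length(rows)]) { rejected <- TRUE; break }
    if (step < tol) { converged <- TRUE; break }
  }
  d2 <- (X - cx)^2 + (Y - cy)^2
  inside <- d2 <= int_radius^2
  intensity <- sum(win[inside])
  n_disk <- sum(inside)
  snr <- if (bg_sd > 0) intensity / (bg_sd * sqrt(n_disk)) else 0
  pos <- win[inside] > 0
  sig <- if (any(pos)) {
    sqrt(sum(win[inside][pos] * d2[inside][pos]) / sum(win[inside][pos]) / 2)
  } else 0
  if (rejected) { intensity <- 0; snr <- 0 }
  c(cx, cy, intensity, bg, sig,
    if (is.na(snr)) 0 else snr, as.numeric(converged), as.numeric(rejected))
}

#' Threshold foci by signal-to-noise ratio
#'
#' Keeps foci with `snr >= threshold`, preserving order.
#'
#' @param foci data.frame with an `snr` column.
#' @param threshold non-negative SNR threshold.
#' @return the retained subset.
#' @export
filter_by_snr <- function(foci, threshold) {
  stopifnot(threshold >= 0)
  out <- foci[foci$snr >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaussian smoothing via FFT with edge renormalisation so flat regions
# stay flat at the borders. make_smoother caches the kernel transform and
# the edge normaliser for repeated frames of one geometry.
make_smoother <- function(h, w, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k1 <- stats::dnorm(-r:r, sd = sigma_px)
  kern <- outer(k1, k1) / sum(outer(k1, k1))
  kh <- nrow(kern)
  ph <- stats::nextn(h + kh - 1, 2)
  pw <- stats::nextn(w + kh - 1, 2)
  b <- matrix(0, ph, pw); b[1:kh, 1:kh] <- kern
  fk <- stats::fft(b)
  r0 <- (kh - 1) / 2
  conv <- function(m) {
    a <- matrix(0, ph, pw); a[1:h, 1:w] <- m
    cc <- Re(stats::fft(stats::fft(a) * fk, inverse = TRUE)) / (ph * pw)
    cc[(r0 + 1):(r0 + h), (r0 + 1):(r0 + w)]
  }
  norm <- conv(matrix(1, h, w))
  function(m) conv(m) / norm
}

gaussian_smooth <- function(m, sigma_px) make_smoother(nrow(m), ncol(m), sigma_px)(m)

#' Detect and localize foci in every frame of a stack
#'
#' Candidates are found on a matched-filtered copy of each frame (Gaussian
#' smoothing with the PSF sigma — the standard matched filter for
#' diffraction-limited spots, which makes the candidate gate photon- rather
#' than quantisation-limited), then refined by [gaussian_mask_fit()] on the
#' raw frame. Rejected, non-converged and over-wide fits are dropped and
#' the SNR threshold applied.
#'
#' @param stack an [image_stack()].
#' @param config a [patch_config()].
#' @return data.frame of foci: `frame` (0-based), sub-pixel `x_px`, `y_px`,
#'   `I`, `bg`, `sigma_px`, `snr`.
#' @export
detect_foci <- function(stack, config = patch_config()) {
  sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / stack$pixel_size_nm
  out <- vector("list", n_frames(stack))
  smoother <- make_smoother(dim(stack$frames)[1], dim(stack$frames)[2], sigma_px)
  for (t in seq_len(n_frames(stack)) - 1L) {
    fr <- get_frame(stack, t)
    cand <- detect_candidates(smoother(fr),
                              radius = config$detect_radius_px,
                              bg_box = config$bg_box_px,
                              min_sd = config$candidate_min_sd)
    if (nrow(cand) == 0) next
    fits <- vapply(seq_len(nrow(cand)), function(i)
      gmask_fit_core(fr, c(cand$x_px[i], cand$y_px[i]),
                     radius = config$detect_radius_px,
                     bg_box = config$bg_box_px, sigma_px = sigma_px,
                     tol = config$mask_tol_px,
                     max_iter = config$mask_max_iter,
                     int_radius = config$integration_radius_px,
                     bg_annulus = config$bg_annulus_px), numeric(8))
    ok <- fits[7, ] == 1 & fits[8, ] == 0 &
      fits[5, ] <= config$max_width_factor * sigma_px
    if (!any(ok)) next
    out[[t + 1L]] <- cbind(t, t(fits[1:6, ok, drop = FALSE]))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      I = numeric(0), bg = numeric(0), sigma_px = numeric(0),
                      snr = numeric(0)))
  out <- data.frame(frame = as.integer(out[, 1]), x_px = out[, 2],
                    y_px = out[, 3], I = out[, 4], bg = out[, 5],
                    sigma_px = out[, 6], snr = out[, 7])
  out <- filter_by_snr(out, config$snr_threshold)
  out <- out[order(out$frame, out$y_px, out$x_px),
             c("frame", "x_px", "y_px", "I", "bg", "sigma_px", "snr")]
  rownames(out) <- NULL
  out
}

#' Calibrate the SNR threshold on blank frames
#'
#' Simulates frames containing only the background noise model (Poisson
#' background plus Gaussian read noise), runs the full candidate + fit
#' chain, and returns the smallest threshold at which no more than
#' `target_fp_per_100` fitted foci per 100 blank frames survive.
#'
#' @param config a [patch_config()]; the candidate pre-gate and fit
#'   parameters are taken from it.
#' @param bg,read_noise_sd blank-frame noise model (counts).
#' @param n_frames_cal number of blank frames to simulate.
#' @param dim_hw blank frame size.
#' @param target_fp_per_100 tolerated false positives per 100 frames.
#' @param seed integer random seed.
#' @return the calibrated threshold (numeric scalar).
#' @export
calibrate_snr_threshold <- function(config = patch_config(), bg = 3,
                                    read_noise_sd = 1, n_frames_cal = 200,
                                    dim_hw = c(64, 64),
                                    target_fp_per_100 = 1, seed = 1L) {
  set.seed(as.integer(seed))
  sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / config$pixel_size_nm
  snrs <- numeric(0)
  for (i in seq_len(n_frames_cal)) {
    fr <- matrix(pmax(0, round(stats::rpois(prod(dim_hw), bg) +
                               stats::rnorm(prod(dim_hw), 0, read_noise_sd))),
                 dim_hw[1], dim_hw[2])
    cand <- detect_candidates(gaussian_smooth(fr, sigma_px),
                              radius = config$detect_radius_px,
                              bg_box = config$bg_box_px,
                              min_sd = config$candidate_min_sd)
    if (nrow(cand) == 0) next
    fits <- vapply(seq_len(nrow(cand)), function(j)
      gmask_fit_core(fr, c(cand$x_px[j], cand$y_px[j]),
                     radius = config$detect_radius_px,
                     bg_box = config$bg_box_px, sigma_px = sigma_px,
                     tol = config$mask_tol_px,
                     max_iter = config$mask_max_iter,
                     int_radius = config$integration_radius_px,
                     bg_annulus = config$bg_annulus_px), numeric(8))
    ok <- fits[7, ] == 1 & fits[8, ] == 0 &
      fits[5, ] <= config$max_width_factor * sigma_px
    snrs <- c(snrs, fits[6, ok])
  }
  allowed <- floor(n_frames_cal * target_fp_per_100 / 100)
  if (length(snrs) <= allowed) return(0)
  s <- sort(snrs, decreasing = TRUE)
  if (allowed == 0) s[1] + 1e-6 else (s[allowed] + s[allowed + 1]) / 2
}
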