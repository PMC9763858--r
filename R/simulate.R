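#' Spatial point pattern container
#'
#' Centroid coordinates in physical units (nm) together with the
#' region-of-interest (cell boundary) they live in. The ROI is either a
#' rectangle `list(type = "rect", w_nm, h_nm)` (origin at 0,0) or a mask
#' `list(type = "mask", mask, pixel_size_nm)` with non-zero pixels inside
#' the cell.
#'
#' @param points_nm two-column matrix (x_nm, y_nm).
#' @param roi region description, see above.
#' @return an object of class `point_pattern` with fields `points`, `roi`
#'   and `area_um2`.
#' @export
point_pattern <- function(points_nm, roi) {
  points_nm <- matrix(as.numeric(points_nm), ncol = 2,
                      dimnames = list(NULL, c("x_nm", "y_nm")))
  if (identical(roi$type, "rect")) {
    stopifnot(roi$w_nm > 0, roi$h_nm > 0)
    area <- roi$w_nm * roi$h_nm / 1e6
    if (nrow(points_nm) > 0) {
      ok <- points_nm[, 1] >= 0 & points_nm[, 1] <= roi$w_nm &
            points_nm[, 2] >= 0 & points_nm[, 2] <= roi$h_nm
      if (!all(ok)) stop("points outside rectangular ROI")
    }
  } else if (identical(roi$type, "mask")) {
    stopifnot(is.matrix(roi$mask), roi$pixel_size_nm > 0)
    area <- sum(roi$mask != 0) * roi$pixel_size_nm^2 / 1e6
  } else stop("roi$type must be 'rect' or 'mask'")
  if (area <= 0) stop("ROI area must be positive")
  structure(list(points = points_nm, roi = roi, area_um2 = area),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in %.2f um^2 (%s ROI), density %.3g /um^2\n",
              nrow(x$points), x$area_um2, x$roi$type,
              nrow(x$points) / x$area_um2))
  invisible(x)
}

roi_contains <- function(roi, x_nm, y_nm) {
  if (identical(roi$type, "rect")) {
    x_nm >= 0 & x_nm <= roi$w_nm & y_nm >= 0 & y_nm <= roi$h_nm
  } else {
    px <- roi$pixel_size_nm
    col <- floor(x_nm / px) + 1L
    row <- floor(y_nm / px) + 1L
    ok <- col >= 1 & col <= ncol(roi$mask) & row >= 1 & row <= nrow(roi$mask)
    ins <- rep(FALSE, length(x_nm))
    ins[ok] <- roi$mask[cbind(row[ok], col[ok])] != 0
    ins
  }
}

#' Simulate a 2D point pattern with known ground truth
#'
#' Three generators matching the simulated controls used to validate the
#' clustering statistics: complete spatial randomness (homogeneous Poisson),
#' a square lattice with isotropic Gaussian jitter of rms displacement half
#' the lattice spacing (per-axis sd `a / (2 sqrt(2))`), and a Thomas-type
#' clustered process (Poisson parents, Poisson-many Gaussian offspring).
#' Points falling outside the region are discarded.
#'
#' @param kind `"csr"`, `"lattice_jitter"` or `"clustered"`.
#' @param region_nm rectangle size `c(w_nm, h_nm)`.
#' @param lambda_per_um2 CSR intensity (points per um^2).
#' @param spacing_nm lattice spacing a (nm).
#' @param jitter_rms_nm rms of the 2D lattice jitter; defaults to
#'   `spacing_nm / 2`.
#' @param parent_per_um2,mean_offspring,offspring_sd_nm Thomas process
#'   parameters.
#' @param seed integer random seed.
#' @return `list(pattern = point_pattern, truth = list(...))` where `truth`
#'   records the generating parameters (and parent locations for the
#'   clustered kind).
#' @export
simulate_point_pattern <- function(kind = c("csr", "lattice_jitter", "clustered"),
                                   region_nm = c(10000, 10000),
                                   lambda_per_um2 = 2,
                                   spacing_nm = 500,
                                   jitter_rms_nm = NULL,
                                   parent_per_um2 = 0.2,
                                   mean_offspring = 10,
                                   offspring_sd_nm = 150,
                                   seed = 1L) {
  kind <- match.arg(kind)
  w <- region_nm[1]; h <- region_nm[2]
  stopifnot(w > 0, h > 0)
  roi <- list(type = "rect", w_nm = w, h_nm = h)
  area_um2 <- w * h / 1e6
  set.seed(as.integer(seed))
  truth <- list(kind = kind, seed = as.integer(seed))
  if (kind == "csr") {
    if (lambda_per_um2 <= 0) stop("lambda_per_um2 must be positive")
    n <- stats::rpois(1, lambda_per_um2 * area_um2)
    pts <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    truth$lambda_per_um2 <- lambda_per_um2
  } else if (kind == "lattice_jitter") {
    if (spacing_nm <= 0) stop("spacing_nm must be positive")
    if (is.null(jitter_rms_nm)) jitter_rms_nm <- spacing_nm / 2
    if (jitter_rms_nm < 0) stop("jitter_rms_nm must be >= 0")
    gx <- seq(spacing_nm / 2, w - spacing_nm / 2 + 1e-9, by = spacing_nm)
    gy <- seq(spacing_nm / 2, h - spacing_nm / 2 + 1e-9, by = spacing_nm)
    pts <- as.matrix(expand.grid(gx, gy))
    sd_ax <- jitter_rms_nm / sqrt(2)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, sd_ax), ncol = 2)
    truth$spacing_nm <- spacing_nm
    truth$jitter_rms_nm <- jitter_rms_nm
  } else {
    if (parent_per_um2 <= 0 || mean_offspring <= 0 || offspring_sd_nm <= 0)
      stop("Thomas parameters must be positive")
    n_par <- stats::rpois(1, parent_per_um2 * area_um2)
    par_xy <- cbind(stats::runif(n_par, 0, w), stats::runif(n_par, 0, h))
    n_off <- stats::rpois(n_par, mean_offspring)
    pts <- matrix(numeric(0), ncol = 2)
    if (n_par > 0 && sum(n_off) > 0) {
      cx <- rep(par_xy[, 1], n_off)
      cy <- rep(par_xy[, 2], n_off)
      pts <- cbind(cx + stats::rnorm(length(cx), 0, offspring_sd_nm),
                   cy + stats::rnorm(length(cy), 0, offspring_sd_nm))
    }
    truth$parents_nm <- par_xy
    truth$parent_per_um2 <- parent_per_um2
    truth$mean_offspring <- mean_offspring
    truth$offspring_sd_nm <- offspring_sd_nm
  }
  if (nrow(pts) > 0) {
    keep <- roi_contains(roi, pts[, 1], pts[, 2])
    pts <- pts[keep, , drop = FALSE]
  }
  list(pattern = point_pattern(pts, roi), truth = truth)
}

#' Simulate an image stack of photobleaching molecular assemblies
#'
#' Each assembly is a set of fluorophores at a fixed position, rendered per
#' frame as a pixel-integrated 2D Gaussian (sd = PSF sigma) whose integrated
#' intensity equals (surviving molecules) x (unitary brightness `i1`). Each
#' molecule bleaches independently and irreversibly with constant per-frame
#' probability `p_bleach` (geometric survival; all molecules are emitting in
#' frame 0, so the frame-0 integrated intensity is exactly `N * i1`). With
#' `noise = TRUE`, pixel values are `Poisson(signal + bg)` plus Gaussian
#' read noise, rounded to whole non-negative counts as a camera would
#' digitise them; noiseless stacks carry the exact expected signal plus
#' `bg`.
#'
#' @param n_assemblies number of assemblies (ignored when
#'   `stoichiometries` or `positions_px` give explicit truth).
#' @param stoichiometries integer molecule counts per assembly; default
#'   draws dimeric values `2 * k`, `k` uniform on `1..18`.
#' @param positions_px optional two-column matrix of (x, y) 0-based pixel
#'   positions; default places assemblies uniformly with a minimum pairwise
#'   separation of two PSF FWHM and a window-sized border margin.
#' @param dim_hw frame size `c(H, W)` in pixels.
#' @param n_frames frames to render.
#' @param i1 unitary fluorophore brightness (integrated counts).
#' @param p_bleach per-frame per-molecule bleach probability.
#' @param bg mean background (counts / pixel), must be non-negative.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param noise logical; disable for exact noiseless fixtures.
#' @param pixel_size_nm,psf_sigma_nm instrument geometry; defaults mimic
#'   53 nm pixels and a 180 nm FWHM PSF (sigma 76.4 nm).
#' @param margin_px border kept free of assemblies.
#' @param min_sep_px minimum assembly separation; default two PSF FWHM.
#' @param seed integer random seed.
#' @return `list(stack, truth, bleach_frames, params)`: `truth` is a
#'   data.frame (assembly_id, x_px, y_px, x_nm, y_nm, stoichiometry),
#'   `bleach_frames` a list of per-molecule bleach frames (molecule m is
#'   emitting in frames `t < bleach_frames[m]`; `Inf` when `p_bleach = 0`).
#' @export
simulate_assembly_stack <- function(n_assemblies = 50,
                                    stoichiometries = NULL,
                                    positions_px = NULL,
                                    dim_hw = c(256, 256),
                                    n_frames = 300,
                                    i1 = 100,
                                    p_bleach = 0.03,
                                    bg = 1,
                                    read_noise_sd = 0.5,
                                    noise = TRUE,
                                    pixel_size_nm = 53,
                                    psf_sigma_nm = 180 / (2 * sqrt(2 * log(2))),
                                    margin_px = 12,
                                    min_sep_px = NULL,
                                    seed = 1L) {
  stopifnot(n_frames >= 1, i1 > 0, p_bleach >= 0, p_bleach < 1)
  if (bg < 0) stop("background must be non-negative")
  h <- dim_hw[1]; w <- dim_hw[2]
  sigma_px <- psf_sigma_nm / pixel_size_nm
  if (sigma_px < 0.5)
    warning("PSF sigma below 0.5 px: spots are undersampled")
  fwhm_px <- sigma_px * 2 * sqrt(2 * log(2))
  if (is.null(min_sep_px)) min_sep_px <- 2 * fwhm_px
  set.seed(as.integer(seed))
  if (!is.null(positions_px)) {
    positions_px <- matrix(positions_px, ncol = 2)
    n_assemblies <- nrow(positions_px)
  }
  if (is.null(stoichiometries))
    stoichiometries <- 2L * sample.int(18L, n_assemblies, replace = TRUE)
  n_assemblies <- length(stoichiometries)
  if (is.null(positions_px)) {
    positions_px <- place_min_sep(n_assemblies, w, h, margin_px, min_sep_px)
  }
  if (any(positions_px[, 1] < 0 | positions_px[, 1] > w - 1 |
          positions_px[, 2] < 0 | positions_px[, 2] > h - 1))
    stop("assemblies must fit inside the frame")

  # per-molecule bleach frames: molecule emits in frames t < bleach_frame
  bleach_frames <- lapply(stoichiometries, function(n) {
    if (p_bleach == 0) rep(Inf, n) else stats::rgeom(n, p_bleach) + 1
  })

  # pixel-integrated unit PSF footprint per assembly
  half <- ceiling(5 * sigma_px) + 1
  foots <- vector("list", n_assemblies)
  for (a in seq_len(n_assemblies)) {
    x0 <- positions_px[a, 1]; y0 <- positions_px[a, 2]
    cols <- max(0, round(x0) - half):min(w - 1, round(x0) + half)
    rows <- max(0, round(y0) - half):min(h - 1, round(y0) + half)
    fx <- stats::pnorm((cols + 0.5 - x0) / sigma_px) -
          stats::pnorm((cols - 0.5 - x0) / sigma_px)
    fy <- stats::pnorm((rows + 0.5 - y0) / sigma_px) -
          stats::pnorm((rows - 0.5 - y0) / sigma_px)
    foots[[a]] <- list(rows = rows + 1L, cols = cols + 1L, fp = outer(fy, fx))
  }

  frames <- array(0, dim = c(h, w, n_frames))
  alive_mat <- vapply(seq_len(n_assemblies), function(a)
    vapply(0:(n_frames - 1), function(t) sum(bleach_frames[[a]] > t), numeric(1)),
    numeric(n_frames))
  alive_mat <- matrix(alive_mat, nrow = n_frames)
  for (t in seq_len(n_frames)) {
    fr <- matrix(bg, h, w)
    for (a in seq_len(n_assemblies)) {
      na <- alive_mat[t, a]
      if (na > 0) {
        f <- foots[[a]]
        fr[f$rows, f$cols] <- fr[f$rows, f$cols] + na * i1 * f$fp
      }
    }
    if (noise) {
      fr <- stats::rpois(length(fr), fr) + stats::rnorm(length(fr), 0, read_noise_sd)
      fr <- matrix(pmax(0, round(fr)), h, w)
    }
    frames[, , t] <- fr
  }
  truth <- data.frame(assembly_id = seq_len(n_assemblies),
                      x_px = positions_px[, 1],
                      y_px = positions_px[, 2],
                      x_nm = positions_px[, 1] * pixel_size_nm,
                      y_nm = positions_px[, 2] * pixel_size_nm,
                      stoichiometry = stoichiometries)
  list(stack = image_stack(frames, pixel_size_nm = pixel_size_nm),
       truth = truth,
       bleach_frames = bleach_frames,
       params = list(i1 = i1, p_bleach = p_bleach, bg = bg,
                     read_noise_sd = read_noise_sd, psf_sigma_px = sigma_px,
                     noise = noise, seed = as.integer(seed)))
}

# Uniform placement with minimum pairwise separation (simple rejection).
place_min_sep <- function(n, w, h, margin, min_sep) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > 100000) stop("cannot place assemblies at the requested separation")
    x <- stats::runif(1, margin, w - 1 - margin)
    y <- stats::runif(1, margin, h - 1 - margin)
    if (placed == 0 ||
        min((pts[1:placed, 1] - x)^2 + (pts[1:placed, 2] - y)^2) >= min_sep^2) {
      placed <- placed + 1
      pts[placed, ] <- c(x, y)
    }
  }
  pts
}

#' Simulate a piecewise-constant intensity trace
#'
#' Fixture generator for step-detection validation: a trace holding each of
#' `levels[k]` for `lengths[k]` samples with additive Gaussian noise.
#'
#' @param levels plateau values.
#' @param lengths samples per plateau (recycled to `length(levels)`).
#' @param noise_sd Gaussian noise sd; must be non-negative.
#' @param seed integer random seed.
#' @return `list(trace, truth)`; `truth$change_points` holds the 0-based
#'   index of the first sample of each plateau after the first.
#' @export
simulate_intensity_trace <- function(levels, lengths = 50, noise_sd = 0,
                                     seed = 1L) {
  if (length(levels) == 0) stop("levels must be nonempty")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  lengths <- rep_len(lengths, length(levels))
  truth_vals <- rep(levels, lengths)
  set.seed(as.integer(seed))
  trace <- truth_vals + stats::rnorm(length(truth_vals), 0, noise_sd)
  change_points <- cumsum(lengths)[-length(lengths)]
  list(trace = trace,
       truth = list(levels = levels, lengths = lengths,
                    change_points = change_points))
}
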