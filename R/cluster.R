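# 2D "same" convolution via zero-padded FFT. Kernel dimensions must be odd.
fft_conv2 <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- stats::nextn(h + kh - 1, 2)
  pw <- stats::nextn(w + kw - 1, 2)
  a <- matrix(0, ph, pw); a[1:h, 1:w] <- m
  b <- matrix(0, ph, pw); b[1:kh, 1:kw] <- kern
  cc <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / (ph * pw)
  r0 <- (kh - 1) / 2; c0 <- (kw - 1) / 2
  cc[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  (d <= radius^2) * 1
}

#' Photobleach correction of a z-stack
#'
#' Fits an exponential decay to a reference intensity series (mean
#' intensities of repeated images of the same region) by least squares of
#' `log(mean)` against acquisition index, and scales plane k of the stack
#' by `exp(k / tau)` so that planes of identical content have equal
#' corrected means. A reference that brightens (fitted decay rate < 0) has
#' no admissible exponential-decay fit and is an error; a flat reference
#' gives the identity transform.
#'
#' @param stack an [image_stack()] (planes ordered by acquisition).
#' @param reference numeric vector of reference mean intensities (one per
#'   acquisition index), or an `image_stack` whose plane means are used.
#' @return `list(stack, tau_frames)`: the corrected stack and the fitted
#'   decay constant in acquisition-index units (`Inf` for a flat
#'   reference).
#' @export
bleach_correct_zstack <- function(stack, reference) {
  stopifnot(inherits(stack, "image_stack"))
  means <- if (inherits(reference, "image_stack")) {
    vapply(seq_len(n_frames(reference)) - 1L,
           function(t) mean(get_frame(reference, t)), numeric(1))
  } else as.numeric(reference)
  if (length(means) < 2) stop("reference must contain at least two points")
  if (any(means <= 0)) stop("reference means must be positive")
  k <- seq_along(means) - 1
  fit <- stats::lm(log(means) ~ k)
  slope <- unname(stats::coef(fit)[2])
  if (slope > 1e-12)
    stop("reference intensity increases: no admissible exponential-decay fit")
  tau <- if (slope > -1e-12) Inf else -1 / slope
  out <- stack
  for (t in seq_len(n_frames(stack)) - 1L)
    out$frames[, , t + 1L] <- stack$frames[, , t + 1L] * exp(t / tau)
  list(stack = out, tau_frames = tau)
}

#' Otsu threshold
#'
#' Histogram-based threshold maximising the between-class variance over
#' `n_levels` equal-width bins spanning the data range. Ties resolve to the
#' lowest maximising threshold. Foreground is `value > threshold`.
#'
#' @param x numeric vector or matrix of intensities (non-constant).
#' @param n_levels number of candidate bins (256 reproduces the classic
#'   8-bit formulation).
#' @return the threshold value (a bin edge).
#' @export
otsu_threshold <- function(x, n_levels = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("segmentation error: constant image has no Otsu threshold")
  bin <- pmin(floor((v - lo) / (hi - lo) * n_levels), n_levels - 1)
  h <- tabulate(bin + 1L, nbins = n_levels)
  p <- h / sum(h)
  centers <- lo + (seq_len(n_levels) - 0.5) * (hi - lo) / n_levels
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[n_levels]
  denom <- w0 * (1 - w0)
  bcv <- ifelse(denom > 0, (mt * w0 - m0)^2 / denom, -Inf)
  k <- which.max(bcv[-n_levels])       # threshold between bin k and k+1
  lo + k * (hi - lo) / n_levels
}

# Per-pixel Otsu threshold inside a disk neighbourhood, via a quantised
# level stack and FFT disk convolutions.
local_otsu_threshold <- function(img, radius, n_levels = 64) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) stop("segmentation error: constant image has no Otsu threshold")
  bins <- pmin(floor((img - lo) / (hi - lo) * n_levels), n_levels - 1)
  kern <- disk_kernel(radius)
  h <- nrow(img); w <- ncol(img)
  centers <- lo + (seq_len(n_levels) - 0.5) * (hi - lo) / n_levels
  w0 <- matrix(0, h, w)     # cumulative count below level
  m0 <- matrix(0, h, w)     # cumulative first moment
  ntot <- fft_conv2(matrix(1, h, w), kern)
  # total first moment
  mt <- fft_conv2(matrix(centers[bins + 1L], h, w), kern)
  best <- matrix(-Inf, h, w)
  thr_bin <- matrix(0L, h, w)
  for (l in seq_len(n_levels - 1)) {
    cnt <- fft_conv2((bins == (l - 1)) * 1, kern)
    cnt <- pmax(cnt, 0)
    w0 <- w0 + cnt
    m0 <- m0 + cnt * centers[l]
    omega <- pmin(pmax(w0 / ntot, 0), 1)
    denom <- omega * (1 - omega)
    bcv <- ifelse(denom > 1e-12, (mt / ntot * omega - m0 / ntot)^2 / denom, -Inf)
    upd <- bcv > best
    best[upd] <- bcv[upd]
    thr_bin[upd] <- l
  }
  lo + thr_bin * (hi - lo) / n_levels
}

#' Binarize fluorescent puncta
#'
#' Parallel combination (logical AND) of a global Otsu threshold and a
#' per-pixel local Otsu threshold computed in a rolling disk of radius
#' `local_radius` pixels, followed by removal of connected components
#' smaller than `min_size` pixels (8-connectivity).
#'
#' @param img numeric intensity matrix (non-constant).
#' @param local_radius local Otsu disk radius (px).
#' @param min_size minimum object size kept (px).
#' @param n_levels quantisation levels of the local threshold.
#' @return logical matrix mask.
#' @export
binarize_puncta <- function(img, local_radius = 25, min_size = 4,
                            n_levels = 64) {
  thr_g <- otsu_threshold(img)
  thr_l <- local_otsu_threshold(img, local_radius, n_levels)
  mask <- img > thr_g & img > thr_l
  if (min_size > 1 && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  }
  mask
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- compact[lab[lab > 0]]
  lab
}

# Outer-boundary perimeter of a binary object mask by Moore tracing of the
# 8-connected boundary, with Vossepoel-Smeulders step weights (0.980 per
# axial move, 1.406 per diagonal move), which are close to unbiased for
# smooth digitised contours. Single-pixel objects get the perimeter of a
# unit square.
object_perimeter <- function(m) {
  idx <- which(m != 0)
  if (length(idx) == 1) return(4)
  h <- nrow(m)
  # start: lexicographically first foreground pixel (scanning columns)
  start <- idx[1]
  sr <- (start - 1) %% h + 1
  sc <- (start - 1) %/% h + 1
  # Moore neighbourhood in clockwise order starting from W
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  fg <- function(r, c) r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c] != 0
  n_ax <- 0; n_di <- 0
  r <- sr; c <- sc
  backtrack <- 1L            # came from the west
  repeat {
    found <- FALSE
    k <- backtrack
    for (step in 1:8) {
      k <- (k %% 8) + 1L
      rr <- r + dr[k]; cc2 <- c + dc[k]
      if (fg(rr, cc2)) {
        if (dr[k] == 0 || dc[k] == 0) n_ax <- n_ax + 1 else n_di <- n_di + 1
        # new backtrack: direction pointing back to the previous pixel,
        # advanced so the clockwise scan resumes just after it
        backtrack <- ((k + 3L) %% 8L) + 1L
        r <- rr; c <- cc2
        found <- TRUE
        break
      }
    }
    if (!found) return(4)    # isolated pixel reached via pruning
    if (r == sr && c == sc && (n_ax + n_di) > 1) break
    if (n_ax + n_di > 4 * length(idx)) break   # safety
  }
  0.980 * n_ax + 1.406 * n_di
}

#' Measure binarized objects
#'
#' 8-connected components of the mask with intensity-weighted centroids,
#' pixel and physical areas, corner-cut crack-boundary perimeters,
#' circularity `4 pi A / P^2` and mean intensities.
#'
#' @param mask logical matrix from [binarize_puncta()].
#' @param img intensity matrix (weights the centroids; pass the mask itself
#'   for geometric centroids).
#' @param pixel_size_nm physical pixel size.
#' @return data.frame: `object_id`, `x_px`, `y_px` (0-based sub-pixel
#'   centroid), `x_nm`, `y_nm`, `area_px`, `area_um2`, `perimeter_px`,
#'   `circularity`, `mean_intensity`.
#' @export
analyze_objects <- function(mask, img = NULL, pixel_size_nm = 1) {
  stopifnot(is.matrix(mask))
  if (is.null(img)) img <- mask * 1
  if (!any(mask))
    return(data.frame(object_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), x_nm = numeric(0), y_nm = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      mean_intensity = numeric(0)))
  lab <- label8(mask)
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(id) {
    idx <- which(lab == id)
    rows <- (idx - 1) %% nrow(mask) + 1
    cols <- (idx - 1) %/% nrow(mask) + 1
    wts <- img[idx]
    if (sum(wts) <= 0) wts <- rep(1, length(idx))
    sub <- matrix(0L, max(rows) - min(rows) + 3, max(cols) - min(cols) + 3)
    sub[cbind(rows - min(rows) + 2, cols - min(cols) + 2)] <- 1L
    per <- object_perimeter(sub)
    area <- length(idx)
    data.frame(object_id = id,
               x_px = sum(wts * (cols - 1)) / sum(wts),
               y_px = sum(wts * (rows - 1)) / sum(wts),
               area_px = area,
               perimeter_px = per,
               circularity = 4 * pi * area / per^2,
               mean_intensity = mean(img[idx]))
  })
  out <- do.call(rbind, out)
  out$x_nm <- out$x_px * pixel_size_nm
  out$y_nm <- out$y_px * pixel_size_nm
  out$area_um2 <- out$area_px * pixel_size_nm^2 / 1e6
  rownames(out) <- NULL
  out[, c("object_id", "x_px", "y_px", "x_nm", "y_nm", "area_px", "area_um2",
          "perimeter_px", "circularity", "mean_intensity")]
}

#' 2D number-density map of point centroids
#'
#' Gaussian kernel density estimate of the centroid coordinates, scaled so
#' the map integrates to the number of points, reported per um^2. The grid
#' extends three kernel widths beyond the point bounding box so no mass is
#' clipped.
#'
#' @param pattern a [point_pattern()] (or a two-column nm coordinate
#'   matrix).
#' @param bw_nm Gaussian kernel sd in nm (default 180, the widefield
#'   lateral resolution).
#' @param grid_step_nm grid pitch; default `bw_nm / 3`.
#' @return list of class `density_map`: `x_nm`, `y_nm` (grid centers), `z`
#'   (density, points / um^2, rows = y), `n`.
#' @export
density_map <- function(pattern, bw_nm = 180, grid_step_nm = bw_nm / 3) {
  pts <- if (inherits(pattern, "point_pattern")) pattern$points else pattern
  n <- nrow(pts)
  if (n < 1) stop("density map needs at least one point")
  pad <- 3 * bw_nm
  xr <- range(pts[, 1]) + c(-pad, pad)
  yr <- range(pts[, 2]) + c(-pad, pad)
  gx <- seq(xr[1], xr[2], by = grid_step_nm)
  gy <- seq(yr[1], yr[2], by = grid_step_nm)
  # binned counts convolved with a Gaussian kernel
  bx <- pmin(pmax(round((pts[, 1] - gx[1]) / grid_step_nm), 0), length(gx) - 1)
  by <- pmin(pmax(round((pts[, 2] - gy[1]) / grid_step_nm), 0), length(gy) - 1)
  cnt <- matrix(0, length(gy), length(gx))
  for (i in seq_len(n)) cnt[by[i] + 1, bx[i] + 1] <- cnt[by[i] + 1, bx[i] + 1] + 1
  kr <- ceiling(4 * bw_nm / grid_step_nm)
  kk <- stats::dnorm(seq(-kr, kr) * grid_step_nm, sd = bw_nm) * grid_step_nm
  kern <- outer(kk, kk)
  z <- fft_conv2(cnt, kern) / (grid_step_nm / 1e3)^2   # per um^2
  structure(list(x_nm = gx, y_nm = gy, z = pmax(z, 0), n = n,
                 bw_nm = bw_nm, grid_step_nm = grid_step_nm),
            class = "density_map")
}

#' Ripley K / L / H curves of a point pattern
#'
#' `K(r) = (A / n^2) * sum_i sum_{j != i} e_ij * 1(d_ij <= r)`,
#' `L(r) = sqrt(K(r) / pi)`, `H(r) = L(r) - r`. H is 0 under complete
#' spatial randomness, positive for clustering and negative for dispersion.
#' Edge corrections: `"none"` (e = 1, matches a brute-force pair count
#' exactly), `"translation"` (rectangular ROI only) and `"isotropic"`
#' (Ripley's correction, 1 / fraction of the circle of radius d_ij about
#' point i lying inside the ROI, evaluated by angular sampling so it
#' applies to arbitrary mask ROIs).
#'
#' @param pattern a [point_pattern()] with at least 10 points.
#' @param r_nm radius grid in nm; default 0 to half the equivalent ROI
#'   radius (at most 10 um) in `step_nm` steps. Radii beyond half the ROI
#'   diameter are dropped with a warning.
#' @param correction `"isotropic"`, `"translation"` or `"none"`.
#' @param step_nm default grid step.
#' @param n_angles angular samples for the isotropic correction.
#' @return object of class `ripley_curve`: data.frame with `r_um`,
#'   `K_um2`, `L_um`, `H_um`; attributes `correction`, `n`, `area_um2`.
#' @export
ripley_h <- function(pattern, r_nm = NULL,
                     correction = c("isotropic", "translation", "none"),
                     step_nm = 20, n_angles = 72) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern"))
  pts <- pattern$points
  n <- nrow(pts)
  if (n < 10) stop("Ripley analysis needs at least 10 points")
  area_nm2 <- pattern$area_um2 * 1e6
  roi_radius <- sqrt(area_nm2 / pi)
  r_valid <- if (identical(pattern$roi$type, "rect"))
    min(pattern$roi$w_nm, pattern$roi$h_nm) / 2 else roi_radius
  if (is.null(r_nm)) r_nm <- seq(0, min(10000, roi_radius / 2), by = step_nm)
  if (any(r_nm > r_valid)) {
    warning("radius grid truncated to half the ROI extent")
    r_nm <- r_nm[r_nm <= r_valid]
  }
  d <- as.matrix(stats::dist(pts))
  iu <- which(upper.tri(d))
  dij <- d[iu]
  keep <- dij <= max(r_nm)
  dij <- dij[keep]
  ii <- ((iu - 1) %% n + 1)[keep]    # row index of pair
  jj <- ((iu - 1) %/% n + 1)[keep]   # col index
  if (correction == "none") {
    wij <- rep(2, length(dij))       # both ordered pairs
  } else if (correction == "translation") {
    if (!identical(pattern$roi$type, "rect"))
      stop("translation correction requires a rectangular ROI")
    dx <- abs(pts[ii, 1] - pts[jj, 1])
    dy <- abs(pts[ii, 2] - pts[jj, 2])
    wij <- 2 * area_nm2 / ((pattern$roi$w_nm - dx) * (pattern$roi$h_nm - dy))
  } else {
    wij <- iso_weight(pts, ii, jj, dij, pattern$roi, n_angles) +
           iso_weight(pts, jj, ii, dij, pattern$roi, n_angles)
  }
  # cumulative weighted pair counts on the grid
  ord <- order(dij)
  dsort <- dij[ord]; wsort <- wij[ord]
  cumw <- c(0, cumsum(wsort))
  idx <- findInterval(r_nm, dsort)
  K_nm2 <- area_nm2 / n^2 * cumw[idx + 1]
  L_nm <- sqrt(K_nm2 / pi)
  curve <- data.frame(r_um = r_nm / 1e3,
                      K_um2 = K_nm2 / 1e6,
                      L_um = L_nm / 1e3,
                      H_um = (L_nm - r_nm) / 1e3)
  attr(curve, "correction") <- correction
  attr(curve, "n") <- n
  attr(curve, "area_um2") <- pattern$area_um2
  class(curve) <- c("ripley_curve", "data.frame")
  curve
}

# Ripley isotropic weight for ordered pairs (i -> j): 1 / fraction of the
# circle of radius d centred at point i lying inside the ROI.
iso_weight <- function(pts, ii, jj, dij, roi, n_angles) {
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  frac <- numeric(length(dij))
  for (k in seq_along(dij)) {
    cx <- pts[ii[k], 1] + dij[k] * cos(th)
    cy <- pts[ii[k], 2] + dij[k] * sin(th)
    frac[k] <- mean(roi_contains(roi, cx, cy))
  }
  1 / pmax(frac, 1 / n_angles)
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf("ripley_curve: %d radii to %.3g um, n = %d points, %s correction\n",
              nrow(x), max(x$r_um), attr(x, "n"), attr(x, "correction")))
  invisible(x)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r_um, x$H_um, type = "l", xlab = "r (um)", ylab = "H(r) (um)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Pointwise CSR envelope for Ripley H
#'
#' Simulates `nsim` complete-spatial-randomness patterns with the observed
#' point count in the same ROI and returns the pointwise 95 % envelope of
#' their H curves.
#'
#' @param n point count per simulation.
#' @param roi ROI descriptor (as in [point_pattern()]).
#' @param r_nm radius grid (nm).
#' @param nsim number of simulations.
#' @param correction edge correction passed to [ripley_h()].
#' @param seed integer random seed.
#' @return list `r_um`, `lo_um`, `hi_um` (2.5 % and 97.5 % pointwise
#'   quantiles).
#' @export
csr_envelope <- function(n, roi, r_nm, nsim = 199, correction = "none",
                         seed = 1L) {
  set.seed(as.integer(seed))
  hs <- matrix(NA_real_, nsim, length(r_nm))
  for (s in seq_len(nsim)) {
    pts <- csr_points(n, roi)
    hs[s, ] <- ripley_h(point_pattern(pts, roi), r_nm = r_nm,
                        correction = correction)$H_um
  }
  list(r_um = r_nm / 1e3,
       lo_um = apply(hs, 2, stats::quantile, 0.025),
       hi_um = apply(hs, 2, stats::quantile, 0.975))
}

csr_points <- function(n, roi) {
  if (identical(roi$type, "rect")) {
    cbind(stats::runif(n, 0, roi$w_nm), stats::runif(n, 0, roi$h_nm))
  } else {
    inside <- which(roi$mask != 0)
    pick <- sample(inside, n, replace = TRUE)
    px <- roi$pixel_size_nm
    col <- (pick - 1) %/% nrow(roi$mask)
    row <- (pick - 1) %% nrow(roi$mask)
    cbind((col + stats::runif(n)) * px, (row + stats::runif(n)) * px)
  }
}

#' Modal clustering gradient of a Ripley H curve
#'
#' Gradients are computed pairwise between adjacent grid points of H(r)
#' (both in um, so the gradient is dimensionless) and summarised by the
#' peak of a Gaussian KDE with kernel sd `bw` (default 0.001). Positive
#' modal gradients indicate clustering accumulating with radius.
#'
#' @param curve a `ripley_curve`.
#' @param bw gradient kernel width.
#' @return list of class `clustering_gradient`: `modal_gradient`,
#'   `gradients`, `kde`.
#' @export
clustering_gradient <- function(curve, bw = 0.001) {
  stopifnot(inherits(curve, "ripley_curve"), nrow(curve) >= 3)
  g <- diff(curve$H_um) / diff(curve$r_um)
  gx <- seq(min(g) - 3 * bw, max(g) + 3 * bw, length.out = 2048)
  gy <- gauss_kde(gx, g, bw)
  structure(list(modal_gradient = gx[which.max(gy)], gradients = g,
                 kde = list(x = gx, y = gy), bw = bw),
            class = "clustering_gradient")
}

#' @export
print.clustering_gradient <- function(x, ...) {
  cat(sprintf("modal clustering gradient dH/dr = %.4g (%d gradient values)\n",
              x$modal_gradient, length(x$gradients)))
  invisible(x)
}

#' Nearest-neighbour distance from a Ripley H curve
#'
#' The minimum of H over the initial region of negative H values. H(r)
#' equals -r below the smallest pair distance, so every pattern starts
#' negative; the initial minimum marks where pairs begin to accumulate,
#' i.e. the typical nearest-neighbour separation. The initial region ends
#' where H turns convincingly positive (at least `sustain` consecutive
#' positive grid points — isolated single-pair blips at very small radii
#' flip the sign of H and are not evidence of clustering); if H never does,
#' the whole curve is the initial region. Undefined (with a warning) when
#' the initial region contains no negative H at all.
#'
#' @param curve a `ripley_curve`.
#' @param sustain consecutive positive grid points that end the initial
#'   region.
#' @return the radius (nm) of the initial H minimum, or `NA` if undefined.
#' @export
nearest_neighbor_distance <- function(curve, sustain = 5) {
  stopifnot(inherits(curve, "ripley_curve"))
  h <- curve$H_um
  r <- curve$r_um
  pos_run <- 0
  end <- length(h)
  for (i in seq_along(h)[r > 0]) {
    pos_run <- if (h[i] > 0) pos_run + 1 else 0
    if (pos_run >= sustain) { end <- i - sustain; break }
  }
  seg <- which(r > 0 & seq_along(r) <= end & h < 0)
  if (length(seg) == 0) {
    warning("H(r) not negative in the initial region; nearest-neighbour distance undefined")
    return(NA_real_)
  }
  r[seg[which.min(h[seg])]] * 1e3
}
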