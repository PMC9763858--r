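# Fractional overlap of two equal disks of radius r with centres d apart,
# normalized by one disk's area. 1 at d = 0, 0 at d >= 2r.
disk_overlap_fraction <- function(d, r) {
  f <- numeric(length(d))
  inr <- d < 2 * r
  di <- d[inr]
  f[inr] <- (2 * r^2 * acos(di / (2 * r)) - (di / 2) * sqrt(4 * r^2 - di^2)) /
    (pi * r^2)
  f
}

#' Link per-frame foci into tracks
#'
#' Foci in adjacent frames are linked when their detection disks (radius =
#' one PSF FWHM, centred on each sub-pixel centroid) overlap within
#' `overlap_bounds` (default 75-100 % fractional area intersection) and
#' their intensity ratio `I[t+1] / I[t]` lies within `ratio_bounds`
#' (default 50-200 %). Each focus links to at most one focus in the next
#' frame; admissible pairs are resolved greedily by decreasing overlap,
#' then by intensity ratio closest to 1, then lexicographically by (y, x) —
#' fully deterministic. Unlinked foci start new tracks; there is no gap
#' closing (adjacent frames only). With `link_mode = "distance"` the
#' overlap gate is replaced by an equivalent centre-distance gate (the
#' distances at which disk overlap equals the bounds).
#'
#' @param foci data.frame from [detect_foci()] (`frame`, `x_px`, `y_px`,
#'   `I`, ...).
#' @param config a [patch_config()]; supplies bounds, the PSF FWHM and the
#'   pixel size.
#' @param pixel_size_nm pixel size used to express the FWHM in pixels;
#'   defaults to the config value.
#' @return the foci data.frame with a `track_id` column, ordered by
#'   (track_id, frame).
#' @export
link_foci <- function(foci, config = patch_config(),
                      pixel_size_nm = config$pixel_size_nm) {
  if (nrow(foci) == 0) {
    foci$track_id <- integer(0)
    return(foci)
  }
  fwhm_px <- config$psf_fwhm_nm / pixel_size_nm
  ob <- config$overlap_bounds
  rb <- config$ratio_bounds
  # distance gate equivalent to the overlap bounds
  inv_overlap <- function(f) {
    if (f >= 1) return(0)
    if (f <= 0) return(2 * fwhm_px)
    stats::uniroot(function(d) disk_overlap_fraction(d, fwhm_px) - f,
                   c(0, 2 * fwhm_px))$root
  }
  d_hi <- inv_overlap(ob[1])   # larger distance = smaller overlap
  d_lo <- inv_overlap(ob[2])

  foci <- foci[order(foci$frame, foci$y_px, foci$x_px), , drop = FALSE]
  rownames(foci) <- NULL
  n <- nrow(foci)
  track_id <- rep(NA_integer_, n)
  next_id <- 0L
  frames <- sort(unique(foci$frame))
  idx_by_frame <- split(seq_len(n), foci$frame)

  for (fi in seq_along(frames)) {
    cur <- idx_by_frame[[as.character(frames[fi])]]
    new_tracks <- cur[is.na(track_id[cur])]
    if (length(new_tracks) > 0) {
      track_id[new_tracks] <- next_id + seq_along(new_tracks)
      next_id <- next_id + length(new_tracks)
    }
    if (fi == length(frames) || frames[fi + 1] != frames[fi] + 1) next
    nxt <- idx_by_frame[[as.character(frames[fi + 1])]]
    if (length(nxt) == 0) next
    # admissible pairs
    dx <- outer(foci$x_px[cur], foci$x_px[nxt], "-")
    dy <- outer(foci$y_px[cur], foci$y_px[nxt], "-")
    d <- sqrt(dx^2 + dy^2)
    ratio <- outer(foci$I[cur], foci$I[nxt], function(a, b) b / a)
    ov <- matrix(disk_overlap_fraction(as.vector(d), fwhm_px),
                 nrow = length(cur))
    adm <- if (config$link_mode == "overlap") {
      ov >= ob[1] & ov <= ob[2]
    } else {
      d >= d_lo & d <= d_hi
    }
    adm <- adm & ratio >= rb[1] & ratio <= rb[2]
    pairs <- which(adm, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    o <- order(-ov[pairs], abs(log(ratio[pairs])),
               foci$y_px[cur][pairs[, 1]], foci$x_px[cur][pairs[, 1]])
    pairs <- pairs[o, , drop = FALSE]
    used_cur <- logical(length(cur)); used_nxt <- logical(length(nxt))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (used_cur[i] || used_nxt[j]) next
      used_cur[i] <- TRUE; used_nxt[j] <- TRUE
      track_id[nxt[j]] <- track_id[cur[i]]
    }
  }
  # any focus never visited (possible only if frames list was empty) -> own track
  left <- which(is.na(track_id))
  if (length(left) > 0) track_id[left] <- next_id + seq_along(left)
  foci$track_id <- track_id
  foci <- foci[order(foci$track_id, foci$frame), , drop = FALSE]
  rownames(foci) <- NULL
  foci
}

#' Summarise linked foci into a per-track table
#'
#' @param linked output of [link_foci()].
#' @return data.frame with one row per track: `track_id`, `start_frame`,
#'   `length`.
#' @export
track_table <- function(linked) {
  if (nrow(linked) == 0)
    return(data.frame(track_id = integer(0), start_frame = integer(0),
                      length = integer(0)))
  sp <- split(linked$frame, linked$track_id)
  data.frame(track_id = as.integer(names(sp)),
             start_frame = vapply(sp, min, numeric(1)),
             length = lengths(sp),
             row.names = NULL)
}
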