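#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the detection, tracking, stoichiometry
#' and clustering stages into a single validated object. Defaults follow the
#' acquisition geometry of Slimfield/PaTCH single-molecule imaging (53 nm
#' pixels, 180 nm lateral resolution) and the fixed analysis constants used
#' throughout: 8 px detection radius, 17 px background window, 75-100 %
#' linking overlap, 50-200 % intensity ratio, 5 extrapolation frames, 10
#' frame stoichiometry gate, 0.6 molecule stoichiometry kernel width, 0.001
#' gradient kernel width, 25 px local Otsu radius and 180 nm density kernel
#' width.
#'
#' @param pixel_size_nm physical pixel size in nm.
#' @param frame_interval_s time between frames in seconds.
#' @param psf_fwhm_nm full width at half maximum of the point spread
#'   function in nm; the Gaussian mask sd is `psf_fwhm_nm / 2.3548`.
#' @param detect_radius_px radius (px) of the disk in which a candidate must
#'   be the strict local maximum.
#' @param bg_box_px side (px, odd) of the square local-background window.
#' @param integration_radius_px radius (px) of the disk over which the
#'   background-subtracted integrated intensity is summed; at least 4 PSF
#'   sigma so that > 99.9 % of the spot mass is captured while collecting
#'   far less background noise than the full detection disk.
#' @param bg_annulus_px side (px, odd) of the square region around each
#'   focus, excluding the detection disk, from which the local background
#'   level and noise are estimated (with one 3-sigma clipping pass to
#'   reject neighbouring spots).
#' @param candidate_min_sd candidate pre-gate: peak must exceed the local
#'   background mean by this many local noise standard deviations before a
#'   Gaussian-mask fit is attempted. Purely a speed gate; final acceptance
#'   is by `snr_threshold`.
#' @param max_width_factor width gate: fitted foci with second-moment
#'   width above `max_width_factor` times the nominal PSF sigma are
#'   rejected as not diffraction-limited (noise blobs fit to wide, flat
#'   profiles). Standard single-particle filtering practice.
#' @param snr_threshold signal-to-noise threshold applied to fitted foci.
#'   The default was calibrated on blank synthetic frames at the default
#'   noise model so that no more than one false positive survives per 100
#'   blank frames (see [calibrate_snr_threshold()]).
#' @param mask_tol_px convergence tolerance (px) of the iterative Gaussian
#'   mask centroid refinement.
#' @param mask_max_iter maximum mask iterations before a focus is flagged
#'   non-converged.
#' @param overlap_bounds admissible fractional disk-overlap range for
#'   linking foci across adjacent frames.
#' @param ratio_bounds admissible intensity-ratio range `I[t+1]/I[t]` for
#'   linking.
#' @param link_mode `"overlap"` (fractional area intersection of two disks
#'   of radius one PSF FWHM) or `"distance"` (centre-distance gate at the
#'   equivalent radius).
#' @param n_extrap_frames number of initial track frames used for the linear
#'   extrapolation of initial intensity.
#' @param max_start_frame tracks must start within this many frames of first
#'   laser exposure to enter stoichiometry estimates.
#' @param stoich_kernel_width Gaussian kernel sd (molecules) for
#'   stoichiometry and interval KDEs.
#' @param gradient_kernel_width Gaussian kernel sd for the Ripley H gradient
#'   KDE (dimensionless; r and H both in um).
#' @param ck_window Chung-Kennedy forward/backward window length (samples).
#' @param ck_exponent Chung-Kennedy variance-weight exponent p.
#' @param min_step_frac minimum photobleaching step size as a fraction of
#'   the unitary brightness estimate.
#' @param postbleach_frac "sufficient photobleaching" rule: post-bleach
#'   frames are those after total in-mask intensity first falls below this
#'   fraction of its initial value. The mean number of surviving molecules
#'   per assembly at the knee is roughly this fraction times the mean
#'   initial stoichiometry, so it must stay below `1 / mean(S)` for
#'   post-bleach foci to be predominantly single fluorophores; 0.05 covers
#'   mean stoichiometries up to ~20 molecules.
#' @param otsu_local_radius_px disk radius (px) of the local Otsu threshold.
#' @param min_object_px minimum connected-component size (px) kept after
#'   binarization.
#' @param density_kernel_width_nm kernel sd (nm) of the 2D number-density
#'   KDE; defaults to the widefield lateral resolution.
#' @param ripley_step_nm radius grid step (nm) for Ripley curves.
#' @param ripley_correction `"isotropic"`, `"translation"` or `"none"`.
#' @param seed integer random seed recorded in every output.
#' @return an object of class `patch_config` (a validated named list).
#' @export
patch_config <- function(pixel_size_nm = 53,
                         frame_interval_s = 1 / 77,
                         psf_fwhm_nm = 180,
                         detect_radius_px = 8,
                         bg_box_px = 17,
                         integration_radius_px = 6,
                         bg_annulus_px = 25,
                         candidate_min_sd = 2.5,
                         max_width_factor = 1.8,
                         snr_threshold = 3.2,
                         mask_tol_px = 0.01,
                         mask_max_iter = 50,
                         overlap_bounds = c(0.75, 1.00),
                         ratio_bounds = c(0.50, 2.00),
                         link_mode = c("overlap", "distance"),
                         n_extrap_frames = 5,
                         max_start_frame = 10,
                         stoich_kernel_width = 0.6,
                         gradient_kernel_width = 0.001,
                         ck_window = 5,
                         ck_exponent = 2,
                         min_step_frac = 0.5,
                         postbleach_frac = 0.05,
                         otsu_local_radius_px = 25,
                         min_object_px = 4,
                         density_kernel_width_nm = 180,
                         ripley_step_nm = 20,
                         ripley_correction = c("isotropic", "translation", "none"),
                         seed = 1L) {
  cfg <- list(
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    psf_fwhm_nm = psf_fwhm_nm,
    detect_radius_px = detect_radius_px,
    bg_box_px = bg_box_px,
    integration_radius_px = integration_radius_px,
    bg_annulus_px = bg_annulus_px,
    candidate_min_sd = candidate_min_sd,
    max_width_factor = max_width_factor,
    snr_threshold = snr_threshold,
    mask_tol_px = mask_tol_px,
    mask_max_iter = mask_max_iter,
    overlap_bounds = as.numeric(overlap_bounds),
    ratio_bounds = as.numeric(ratio_bounds),
    link_mode = match.arg(link_mode),
    n_extrap_frames = n_extrap_frames,
    max_start_frame = max_start_frame,
    stoich_kernel_width = stoich_kernel_width,
    gradient_kernel_width = gradient_kernel_width,
    ck_window = ck_window,
    ck_exponent = ck_exponent,
    min_step_frac = min_step_frac,
    postbleach_frac = postbleach_frac,
    otsu_local_radius_px = otsu_local_radius_px,
    min_object_px = min_object_px,
    density_kernel_width_nm = density_kernel_width_nm,
    ripley_step_nm = ripley_step_nm,
    ripley_correction = match.arg(ripley_correction),
    seed = as.integer(seed)
  )
  class(cfg) <- "patch_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks ordering of bound pairs, positivity of widths and radii, and basic
#' type sanity. Called by [patch_config()]; exported so configurations read
#' from YAML are checked the same way.
#'
#' @param cfg a `patch_config`.
#' @return `cfg`, invisibly, or an error describing the first violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "patch_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  pos <- c("pixel_size_nm", "frame_interval_s", "psf_fwhm_nm",
           "detect_radius_px", "bg_box_px", "mask_tol_px",
           "stoich_kernel_width", "gradient_kernel_width", "ck_window",
           "min_step_frac", "postbleach_frac", "otsu_local_radius_px",
           "density_kernel_width_nm", "ripley_step_nm")
  for (p in pos) chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 && cfg[[p]] > 0,
                     paste(p, "must be a positive scalar"))
  chk(cfg$bg_box_px %% 2 == 1, "bg_box_px must be odd")
  chk(cfg$bg_annulus_px %% 2 == 1 && cfg$bg_annulus_px > 2 * cfg$integration_radius_px,
      "bg_annulus_px must be odd and wider than the integration disk")
  chk(cfg$integration_radius_px > 0, "integration_radius_px must be positive")
  chk(length(cfg$overlap_bounds) == 2 && diff(cfg$overlap_bounds) >= 0 &&
        cfg$overlap_bounds[1] >= 0 && cfg$overlap_bounds[2] <= 1,
      "overlap_bounds must be an ordered pair in [0, 1]")
  chk(length(cfg$ratio_bounds) == 2 && diff(cfg$ratio_bounds) >= 0 &&
        cfg$ratio_bounds[1] > 0, "ratio_bounds must be an ordered positive pair")
  chk(cfg$snr_threshold >= 0, "snr_threshold must be >= 0")
  chk(cfg$candidate_min_sd >= 0, "candidate_min_sd must be >= 0")
  chk(cfg$max_width_factor > 0, "max_width_factor must be positive")
  chk(cfg$n_extrap_frames >= 2, "n_extrap_frames must be >= 2")
  chk(cfg$max_start_frame >= 1, "max_start_frame must be >= 1")
  chk(cfg$min_object_px >= 1, "min_object_px must be >= 1")
  chk(cfg$mask_max_iter >= 1, "mask_max_iter must be >= 1")
  chk(is.integer(cfg$seed) && length(cfg$seed) == 1, "seed must be a scalar integer")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' The YAML file holds exactly the fields of [patch_config()]; unknown keys
#' are rejected so typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `patch_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(patch_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(patch_config, raw)
}

#' @rdname read_config
#' @param cfg a `patch_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Deterministic configuration hash
#'
#' FNV-1a (64-bit, reported as 16 hex digits) over the serialized canonical
#' field list. Stamped into every output table and report so artifacts can
#' be traced to the exact configuration that produced them.
#'
#' @param cfg a `patch_config`.
#' @return a 16-character hex string.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "patch_config"))
  fields <- unclass(cfg)[order(names(unclass(cfg)))]
  # canonical text rendering (15 significant digits, matching the YAML
  # writer) so a config hashes identically before and after a round trip
  txt <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    vs <- if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
    paste0(k, "=", paste(vs, collapse = ","))
  }, character(1))
  bytes <- utf8ToInt(paste(txt, collapse = ";"))
  fnv1a64(bytes)
}

# 32-bit FNV-1a over a vector of byte values (0-255), run twice with
# different offset bases and concatenated to 16 hex digits. The 32-bit
# multiply is split at 16 bits so every intermediate stays exact in doubles.
fnv1a32 <- function(bytes, offset = 2166136261) {
  h <- offset
  for (b in bytes) {
    low <- h %% 65536
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

fnv1a64 <- function(bytes) {
  h1 <- fnv1a32(bytes, 2166136261)
  h2 <- fnv1a32(bytes, 40389)
  paste0(sprintf("%04x%04x", h1 %/% 65536, h1 %% 65536),
         sprintf("%04x%04x", h2 %/% 65536, h2 %% 65536))
}
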