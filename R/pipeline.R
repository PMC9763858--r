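#' Run pipeline stages in order
#'
#' Orchestrates the two analysis branches over a shared artifact store:
#' the single-molecule branch `simulate -> detect -> track -> stoich` and
#' the clustering branch `binarize -> objects -> ripley`. Each stage
#' consumes named artifacts (supplied via `inputs` or produced by earlier
#' stages), logs one structured line with counts and timing, and adds its
#' outputs to the store. A missing dependency is an orchestration error
#' naming the missing artifact. Tables written to `out_dir` are
#' deterministic for a fixed config and seed and carry the config hash.
#'
#' @param config a [patch_config()].
#' @param stages character vector of stage names, executed in the given
#'   order; the empty vector is a no-op.
#' @param inputs named list of starting artifacts (`stack`, `foci`,
#'   `linked`, `image`, `pattern`, `sim_args`, ...).
#' @param out_dir optional output directory for CSV tables and
#'   `report.json`.
#' @param quiet suppress per-stage log lines.
#' @return list of class `pipeline_report`: `config_hash`, `seed`,
#'   `package_version`, per-stage `counts`, and the final `artifacts`.
#' @export
run_pipeline <- function(config = patch_config(), stages = character(),
                         inputs = list(), out_dir = NULL, quiet = FALSE) {
  validate_config(config)
  known <- c("simulate", "detect", "track", "stoich", "binarize", "objects",
             "ripley")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  art <- inputs
  counts <- list()
  need <- function(what, stage) {
    if (is.null(art[[what]]))
      stop("orchestration error: stage '", stage,
           "' requires missing artifact '", what, "'")
    art[[what]]
  }
  log_line <- function(stage, n, dt) {
    if (!quiet)
      message(sprintf("[patchstoich] stage=%s n=%d elapsed=%.2fs seed=%d",
                      stage, n, dt, config$seed))
  }
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    n <- switch(st,
      simulate = {
        args <- art$sim_args
        if (is.null(args)) args <- list()
        args$seed <- config$seed
        sim <- do.call(simulate_assembly_stack, args)
        art$stack <- sim$stack
        art$truth <- sim$truth
        art$sim <- sim
        nrow(sim$truth)
      },
      detect = {
        stack <- need("stack", "detect")
        art$foci <- detect_foci(stack, config)
        nrow(art$foci)
      },
      track = {
        foci <- need("foci", "track")
        art$linked <- link_foci(foci, config)
        art$tracks <- track_table(art$linked)
        nrow(art$tracks)
      },
      stoich = {
        stack <- need("stack", "stoich")
        linked <- need("linked", "stoich")
        art$calibration <- single_fluorophore_brightness(
          stack, need("foci", "stoich"), linked, "modal_postbleach", config)
        art$stoichiometry <- track_stoichiometry(linked, art$calibration,
                                                 config,
                                                 t0_frame = stack$t0_frame)
        inc <- art$stoichiometry[art$stoichiometry$included, ]
        if (nrow(inc) >= 3)
          art$periodicity <- periodicity(inc$S, bw = config$stoich_kernel_width,
                                         n_extrap = config$n_extrap_frames)
        nrow(inc)
      },
      binarize = {
        img <- need("image", "binarize")
        art$mask <- binarize_puncta(img, config$otsu_local_radius_px,
                                    config$min_object_px)
        sum(art$mask)
      },
      objects = {
        mask <- need("mask", "objects")
        art$objects <- analyze_objects(mask, art$image, config$pixel_size_nm)
        roi <- art$roi
        if (is.null(roi))
          roi <- list(type = "rect",
                      w_nm = ncol(mask) * config$pixel_size_nm,
                      h_nm = nrow(mask) * config$pixel_size_nm)
        art$pattern <- point_pattern(
          as.matrix(art$objects[, c("x_nm", "y_nm")]), roi)
        nrow(art$objects)
      },
      ripley = {
        pattern <- need("pattern", "ripley")
        art$ripley <- ripley_h(pattern, step_nm = config$ripley_step_nm,
                               correction = config$ripley_correction)
        art$gradient <- clustering_gradient(art$ripley,
                                            bw = config$gradient_kernel_width)
        art$r_nn_nm <- nearest_neighbor_distance(art$ripley)
        nrow(art$ripley)
      })
    counts[[st]] <- n
    log_line(st, n, proc.time()[["elapsed"]] - t0)
  }
  report <- list(config_hash = config_hash(config),
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("patchstoich")),
                 counts = counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(art$foci))
      write_table(art$foci, file.path(out_dir, "foci.csv"), config)
    if (!is.null(art$linked))
      write_table(art$linked, file.path(out_dir, "tracks.csv"), config)
    if (!is.null(art$stoichiometry))
      write_table(art$stoichiometry, file.path(out_dir, "stoichiometry.csv"),
                  config)
    if (!is.null(art$objects))
      write_table(art$objects, file.path(out_dir, "objects.csv"), config)
    if (!is.null(art$ripley))
      write_table(as.data.frame(art$ripley), file.path(out_dir, "ripley.csv"),
                  config)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report$artifacts <- art
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report (config %s, seed %d)\n", x$config_hash, x$seed))
  if (length(x$counts) == 0) cat("  no stages run\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: n = %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
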