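#' Write an output table deterministically
#'
#' All pipeline tables (foci, tracks, Ripley curves, summaries) are written
#' as plain CSV with a header, one row per record, physical units encoded in
#' the column names (`x_px`, `r_um`, ...). Rows are written in the order
#' given; callers sort before writing so re-runs are byte-identical. The
#' producing configuration hash and seed, when supplied, are embedded as
#' leading comment lines so every artifact carries its provenance.
#'
#' @param records a data.frame (possibly empty but with named columns).
#' @param path output path.
#' @param config optional `patch_config`; stamps `#config_hash` and `#seed`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, config = NULL) {
  stopifnot(is.data.frame(records))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(c(paste0("#config_hash=", config_hash(config)),
                 paste0("#seed=", config$seed)), con)
  }
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV path.
#' @return the data.frame; any provenance comment lines are exposed via the
#'   attributes `config_hash` and `seed`.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  for (h in lines[hdr]) {
    kv <- sub("^#", "", h)
    key <- sub("=.*$", "", kv)
    attr(df, key) <- sub("^[^=]*=", "", kv)
  }
  df
}
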