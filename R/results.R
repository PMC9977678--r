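## Result export: one delimited file per named table plus a machine-readable
## run summary, so every number in the outputs can be regenerated from the
## manifest alone.

#' Write result tables and a run summary
#'
#' Each named table becomes one comma-separated file `<name>.csv` in
#' `out_dir`; a `run_summary.json` records the package version, timestamp,
#' the full run configuration (echoed verbatim, including the seed) and any
#' extra summary entries (e.g. per-slide p-values). Numeric values are
#' written at full precision so re-reading reproduces them exactly.
#'
#' @param tables named list of data frames (may be empty).
#' @param out_dir output directory, created if absent.
#' @param config optional [run_config()] echoed into the summary.
#' @param extra optional named list appended to the summary (must be
#'   JSON-serializable).
#' @return the manifest: data frame with `name`, `path`, `n_rows` (the run
#'   summary is listed with `NA` rows), invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, extra = NULL) {
  if (length(tables) && (is.null(names(tables)) || any(!nzchar(names(tables))))) {
    sc_stop("every result table must be named", "spatcoloc_input_error")
  }
  if (anyDuplicated(names(tables))) {
    sc_stop(sprintf("duplicate result table name(s): %s",
                    paste(unique(names(tables)[duplicated(names(tables))]),
                          collapse = ", ")), "spatcoloc_input_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      sc_stop(sprintf("cannot create output directory: %s", out_dir),
              "spatcoloc_io_error")
    }
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    sc_stop(sprintf("output directory is not writable: %s", out_dir),
            "spatcoloc_io_error")
  }
  manifest <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                       qmethod = "double")
    manifest[[length(manifest) + 1L]] <-
      data.frame(name = nm, path = path, n_rows = nrow(df),
                 stringsAsFactors = FALSE)
  }
  summary <- list(
    package = "spatcoloc",
    version = as.character(utils::packageVersion("spatcoloc")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tables = vapply(manifest, function(m) m$name, ""),
    config = if (is.null(config)) NULL else unclass(config))
  if (!is.null(extra)) summary <- c(summary, rapply(extra, function(v) {
    ## named atomic vectors become JSON objects, not bare arrays, so the
    ## summary re-reads with its keys intact
    if (!is.null(names(v))) as.list(v) else v
  }, how = "replace"))
  sum_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest[[length(manifest) + 1L]] <-
    data.frame(name = "run_summary", path = sum_path, n_rows = NA_integer_,
               stringsAsFactors = FALSE)
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  invisible(out)
}
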