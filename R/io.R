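#' Write a sweep trace to delimited text
#'
#' Two tab-separated columns (`time_s`, `current_pa`) preceded by
#' `#key: value` metadata header lines (`sampling_rate_hz`, `holding_mv`,
#' `temp_c`, `rs_start_mohm`, `rs_end_mohm`, `label`).
#'
#' @param trace a [sweep_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#sampling_rate_hz: %.10g", trace$sampling_rate),
    sprintf("#holding_mv: %.10g", trace$holding_potential),
    sprintf("#temp_c: %.10g", trace$temperature),
    sprintf("#rs_start_mohm: %.10g", trace$rs_start),
    sprintf("#rs_end_mohm: %.10g", trace$rs_end),
    sprintf("#label: %s", trace$label),
    "time_s\tcurrent_pa"), con)
  t <- (seq_along(trace$samples) - 1L) / trace$sampling_rate
  utils::write.table(data.frame(time_s = sprintf("%.7f", t),
                                current_pa = sprintf("%.6f", trace$samples)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a sweep trace
#'
#' Reads either the delimited-text dialect written by [write_sweep_tsv()] or
#' the binary dialect written by [write_sweep_rds()]; both yield the same
#' in-memory [sweep_trace()] (the text dialect to its printed precision).
#'
#' @param path input file; `.rds` files are treated as the binary dialect.
#' @return A [sweep_trace()].
#' @export
read_sweep <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    tr <- readRDS(path)
    if (!inherits(tr, "sweep_trace")) stop("not a sweep_trace container: ", path)
    return(tr)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  if (is.null(meta$sampling_rate_hz))
    stop("format error: missing sampling_rate_hz header in ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("time_s", "current_pa") %in% names(dat)))
    stop("format error: expected time_s and current_pa columns in ", path)
  fs <- as.numeric(meta$sampling_rate_hz)
  dt <- diff(dat$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 0.5 / fs)
    stop("format error: non-uniform time column in ", path)
  sweep_trace(samples = dat$current_pa, sampling_rate = fs,
              holding_potential = as.numeric(meta$holding_mv %||% -60),
              temperature = as.numeric(meta$temp_c %||% 35),
              rs_start = as.numeric(meta$rs_start_mohm %||% 8),
              rs_end = as.numeric(meta$rs_end_mohm %||% 8),
              label = meta$label %||% "")
}

#' Write a sweep trace to the binary container dialect
#'
#' Serialises the full trace object (samples plus all acquisition metadata)
#' with R's native binary serialisation; round-trips exactly.
#'
#' @inheritParams write_sweep_tsv
#' @return `path`, invisibly.
#' @export
write_sweep_rds <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  saveRDS(trace, path)
  invisible(path)
}

#' Write / read an analysis table
#'
#' Tab-separated text used for ground-truth tables, per-candidate event
#' tables and per-cell summary tables.
#'
#' @param x data frame.
#' @param path file path.
#' @return `write_table_tsv`: `path` invisibly; `read_table_tsv`: a tibble.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Run the simulate-detect-fit-summarise pipeline end to end
#'
#' Simulates the requested preset cohorts, analyses every cell, and writes a
#' run directory containing per-cell summaries (`cells.tsv`), per-group
#' statistics (`summary.tsv`), an exclusions log (`exclusions.tsv`) and a
#' provenance record (`provenance.json`: presets, seed, analysis options,
#' package version). Deterministic under a fixed seed.
#'
#' @param presets character vector of preset names.
#' @param out_dir output directory; created, must not already contain a run.
#' @param seed integer seed.
#' @param min_events,alpha,window_ms analysis options (see [analyze_cell()]).
#' @param metric per-cell metric summarised per group (default `"tau_w"`).
#' @param n_cells,events_per_cell optional overrides of each preset's cohort
#'   size (mainly for scaled-down runs).
#' @param ... further simulation options passed to [analyze_cohort()].
#' @return The combined per-cell tibble, invisibly.
#' @export
run_pipeline <- function(presets, out_dir, seed = 1, min_events = 50,
                         alpha = 0.05, window_ms = 150, metric = "tau_w",
                         n_cells = NULL, events_per_cell = 120, ...) {
  if (!length(presets)) stop("no presets requested")
  bad <- setdiff(presets, preset_names())
  if (length(bad)) stop("unknown presets: ", paste(bad, collapse = ", "))
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop("output directory already contains files: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- do.call(rbind, lapply(presets, function(p)
    analyze_cohort(preset(p, events_per_cell = events_per_cell), seed = seed,
                   n_cells = n_cells, min_events = min_events, alpha = alpha,
                   window_ms = window_ms, ...)))
  write_table_tsv(cells, file.path(out_dir, "cells.tsv"))
  excl <- cells[!cells$included, c("cell_id", "preset", "n_events",
                                   "exclude_reason")]
  write_table_tsv(excl, file.path(out_dir, "exclusions.tsv"))
  inc <- cells[cells$included, , drop = FALSE]
  smry <- cohort_summarize(inc[[metric]], inc$preset)
  write_table_tsv(smry, file.path(out_dir, "summary.tsv"))
  prov <- list(presets = presets, seed = seed, min_events = min_events,
               alpha = alpha, window_ms = window_ms, metric = metric,
               package_version = as.character(utils::packageVersion("minis")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cells)
}
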