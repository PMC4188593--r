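# Sweep and feature-table I/O.  The canonical on-disk form is a delimited
# text dialect: a '#'-prefixed key<TAB>value header block (sampling_rate_khz,
# mode, units, and metadata), then TAB-separated sample columns time_ms,
# signal, stimulus.  Values round-trip at full double precision.  All
# voltages are mV, currents pA, times ms.

#' @noRd
sweep_units <- function(mode) if (mode == "current_clamp") "mV" else "pA"

#' @noRd
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a sweep set as delimited text
#'
#' One file per sweep, named `<cell_id>_sweep<k>.tsv`, under `dir`.
#'
#' @param sweep_set An `fsi_sweep_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sweeps <- function(sweep_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sweep_set))
  for (k in seq_along(sweep_set$sweeps)) {
    s <- sweep_set[[k]]
    path <- file.path(dir, sprintf("%s_sweep%03d.tsv", s$cell_id, k))
    con <- file(path, "w")
    hdr <- c(sampling_rate_khz = fmt_full(s$sampling_khz),
             mode = s$mode,
             units = sweep_units(s$mode),
             cell_id = s$cell_id,
             group_label = s$group_label)
    meta_flat <- s$meta[vapply(s$meta, function(x)
      is.numeric(x) && length(x) == 1, logical(1))]
    cond_flat <- s$conditions[vapply(s$conditions, function(x)
      (is.numeric(x) || is.character(x)) && length(x) == 1, logical(1))]
    for (nm in names(meta_flat))
      hdr[paste0("meta_", nm)] <- fmt_full(meta_flat[[nm]])
    for (nm in names(cond_flat))
      hdr[paste0("cond_", nm)] <- as.character(cond_flat[[nm]])
    writeLines(paste0("# ", names(hdr), "\t", hdr), con)
    writeLines("time_ms\tsignal\tstimulus", con)
    tm <- sweep_time(s)
    writeLines(paste(fmt_full(tm), fmt_full(s$signal), fmt_full(s$stimulus),
                     sep = "\t"), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

#' @noRd
read_one_sweep_tsv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr_lines), "\t", fixed = TRUE)
  hdr <- setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
  for (key in c("sampling_rate_khz", "mode", "units")) {
    if (!key %in% names(hdr) || is.na(hdr[[key]]))
      fsi_error(sprintf("sweep file %s is missing required header key '%s'",
                        basename(path), key), "missing_header")
  }
  body_start <- length(hdr_lines) + 2L
  dat <- read.table(text = lines[body_start:length(lines)], sep = "\t",
                    col.names = c("time_ms", "signal", "stimulus"))
  meta_keys <- grep("^meta_", names(hdr), value = TRUE)
  meta <- lapply(hdr[meta_keys], as.numeric)
  names(meta) <- sub("^meta_", "", meta_keys)
  cond_keys <- grep("^cond_", names(hdr), value = TRUE)
  conds <- as.list(hdr[cond_keys])
  names(conds) <- sub("^cond_", "", cond_keys)
  if (!is.null(conds$Mg_mM)) conds$Mg_mM <- as.numeric(conds$Mg_mM)
  new_sweep(dat$signal, dat$stimulus,
            sampling_khz = as.numeric(hdr[["sampling_rate_khz"]]),
            mode = hdr[["mode"]],
            cell_id = hdr[["cell_id"]] %||% "cell",
            group_label = hdr[["group_label"]] %||% "custom",
            meta = meta, conditions = conds)
}

#' Read sweeps from disk
#'
#' Reads one sweep file, or every `*.tsv` sweep file in a directory, into an
#' `fsi_sweep_set`.  Only the delimited-text dialect written by
#' [write_sweeps()] is supported; requesting `"nwb"` or `"abf"` raises an
#' unsupported-format error.
#'
#' @param path File or directory.
#' @param format `"tsv"` (supported), `"nwb"` or `"abf"` (unsupported).
#' @return An `fsi_sweep_set`.
#' @export
read_sweeps <- function(path, format = c("tsv", "nwb", "abf")) {
  format <- match.arg(format)
  if (format != "tsv")
    fsi_error(sprintf(
      "format '%s' is not supported by this build; use the tsv dialect",
      format), "unsupported_format")
  files <- if (dir.exists(path))
    sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE)) else path
  if (!length(files) || !all(file.exists(files)))
    fsi_error(sprintf("no sweep files found at %s", path), "missing_file")
  sweeps <- lapply(files, read_one_sweep_tsv)
  new_sweep_set(sweeps, protocol = NULL, cell_id = sweeps[[1]]$cell_id,
                group_label = sweeps[[1]]$group_label)
}

#' Write a feature table as TSV
#'
#' Stable column order `cell_id, group_label, feature, value, units,
#' n_sweeps`; duplicate (cell, feature) keys are an error.
#'
#' @param table Data frame with at least `cell_id`, `feature`, `value`,
#'   `units` columns.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    fsi_error("feature table must be non-empty", "invalid_table")
  if (anyDuplicated(table[c("cell_id", "feature")]))
    fsi_error("duplicate (cell_id, feature) keys in feature table",
              "duplicate_key")
  if (any(!nzchar(table$units)))
    fsi_error("feature units must be non-empty", "invalid_table")
  cols <- c("cell_id", "group_label", "feature", "value", "units", "n_sweeps")
  cols <- cols[cols %in% names(table)]
  out <- table[cols]
  out$value <- fmt_full(out$value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV file.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a cohort manifest as JSON
#' @param manifest Data frame mapping `cell_id` to `group_label` (plus any
#'   extra columns).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
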