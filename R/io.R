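## Canonical on-disk formats: RFC-4180 CSV (UTF-8, "." decimal); TSV
## accepted on read (delimiter sniffed from the header line). Times are
## stored in days, rates serialized in /week.

CLONE_TABLE_COLS <- c("mouse_id", "time_days", "clone_id", "n_basal",
                      "n_suprabasal")
INTENSITY_TABLE_COLS <- c("mouse_id", "time_days", "fov_id", "cell_id",
                          "intensity", "is_leukocyte")

sniff_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

read_table_checked <- function(path, required, numeric_nonneg) {
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    abort_invalid(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")))
  for (col in numeric_nonneg) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0)
      abort_invalid(sprintf("negative values in column '%s' (first at row %d).",
                            col, bad[1]))
  }
  df
}

#' Read a lineage-tracing clone table
#'
#' Reads a CSV/TSV file with one record per clone. Required columns:
#' `mouse_id`, `time_days`, `clone_id`, `n_basal`, `n_suprabasal`; extra
#' columns are preserved. The delimiter is sniffed from the header.
#'
#' @param path file path
#' @return a tibble of validated clone records
#' @export
read_clone_table <- function(path) {
  read_table_checked(path, CLONE_TABLE_COLS, c("n_basal", "n_suprabasal",
                                               "time_days"))
}

#' Read an H2B-GFP intensity table
#'
#' Reads a CSV/TSV file with one record per measured nucleus. Required
#' columns: `mouse_id`, `time_days`, `fov_id`, `cell_id`, `intensity`,
#' `is_leukocyte`; extra columns are preserved.
#'
#' @param path file path
#' @return a tibble of validated intensity records
#' @export
read_intensity_table <- function(path) {
  df <- read_table_checked(path, INTENSITY_TABLE_COLS,
                           c("intensity", "time_days"))
  df$is_leukocyte <- as.logical(df$is_leukocyte)
  df
}

#' Write clone or intensity tables
#'
#' Writes the canonical CSV dialect (RFC 4180, UTF-8). `write_clone_table()`
#' and `write_intensity_table()` validate the required columns first.
#'
#' @param x a clone-table or intensity-table tibble
#' @param path output file path
#' @return `x`, invisibly
#' @export
write_clone_table <- function(x, path) {
  missing <- setdiff(CLONE_TABLE_COLS, names(x))
  if (length(missing) > 0)
    abort_invalid(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")))
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_clone_table
#' @export
write_intensity_table <- function(x, path) {
  missing <- setdiff(INTENSITY_TABLE_COLS, names(x))
  if (length(missing) > 0)
    abort_invalid(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")))
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and wall time of an analysis run as a
#' JSON file next to its outputs, so every artifact can be traced back to
#' the exact invocation that produced it.
#'
#' @param path path of the manifest file to write
#' @param command short name of the operation
#' @param config named list of configuration values (must include any seed)
#' @param elapsed elapsed wall time in seconds (optional)
#' @return the manifest list, invisibly
#' @export
write_run_manifest <- function(path, command, config, elapsed = NULL) {
  manifest <- list(
    command = command,
    config = config,
    package_version = as.character(utils::packageVersion("spclone")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_seconds = elapsed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
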