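# CSV I/O shared by all modules: strict header validation, per-cell numeric
# checking with line numbers, and a config-digest header comment on every
# file the pipeline writes.

.check_columns <- function(df, required, what) {
  if (!is.data.frame(df))
    .stop_invalid(sprintf("%s must be a data frame", what))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(errorCondition(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = c("mrmquant_schema_error", "mrmquant_error")))
  invisible(df)
}

#' Write a CSV with an optional header comment
#'
#' All pipeline outputs are plain CSVs; a `# ...` comment line (typically
#' carrying the run's config digest) may precede the header and is skipped
#' on reading.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param header_comment Optional comment string written as the first line,
#'   prefixed `# `.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a schema-validated CSV
#'
#' Reads a CSV (skipping `#` comment lines), verifies the required columns
#' are present (extra columns are accepted with a warning), and converts
#' the named numeric columns with a row-level error naming the line of the
#' first malformed value.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers.
#' @return Data frame.
#' @export
read_assay_csv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) .stop_invalid(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  .check_columns(df, required, basename(path))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", basename(path),
                    paste(extra, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(df[[col]]) & !is.na(df[[col]]))
    if (length(bad))
      stop(errorCondition(
        sprintf("%s: malformed number '%s' in column '%s' (data row %d)",
                basename(path), df[[col]][bad[1]], col, bad[1]),
        class = c("mrmquant_schema_error", "mrmquant_error")))
    df[[col]] <- vals
  }
  df
}

#' Chromatogram CSV dialect
#'
#' Long format, columns `sample_id, transition_id, time_min, intensity`;
#' one file may hold many samples and transitions.
#'
#' @param traces Long chromatogram data frame (a `sample_id` column is
#'   added as `"sample"` if absent).
#' @param path File path.
#' @param ... Passed to [write_assay_csv()].
#' @return The reader returns the data frame; the writer returns `path`
#'   invisibly.
#' @export
write_chromatograms <- function(traces, path, ...) {
  if (!"sample_id" %in% names(traces)) traces$sample_id <- "sample"
  .check_columns(traces, c("sample_id", "transition_id", "time_min",
                           "intensity"), "chromatogram table")
  write_assay_csv(traces[, c("sample_id", "transition_id", "time_min",
                             "intensity")], path, ...)
}

#' @rdname write_chromatograms
#' @export
read_chromatograms <- function(path) {
  read_assay_csv(path, required = c("sample_id", "transition_id",
                                    "time_min", "intensity"),
                 numeric_cols = c("time_min", "intensity"))
}

#' Sample-results CSV
#'
#' Columns `sample_id, response_ratio, molar_ratio, concentration_nmol_L,
#' qc_pass, flags`.
#'
#' @param results Results data frame from [quantify_batch()] (with QC
#'   merged in).
#' @param path File path.
#' @param ... Passed to [write_assay_csv()].
#' @return The reader returns the data frame; the writer returns `path`.
#' @export
write_results <- function(results, path, ...) {
  .check_columns(results, c("sample_id", "response_ratio", "molar_ratio",
                            "concentration_nmol_L", "qc_pass", "flags"),
                 "results table")
  write_assay_csv(results, path, ...)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_assay_csv(path,
                       required = c("sample_id", "response_ratio",
                                    "molar_ratio", "concentration_nmol_L",
                                    "qc_pass", "flags"),
                       numeric_cols = c("response_ratio", "molar_ratio",
                                        "concentration_nmol_L"))
  df$qc_pass <- as.logical(df$qc_pass)
  df
}

#' Precision-panel CSV
#'
#' Columns `sample_id, day, replicate, concentration_nmol_L`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_precision_panel <- function(path) {
  read_assay_csv(path, required = c("sample_id", "day", "replicate",
                                    "concentration_nmol_L"),
                 numeric_cols = c("day", "replicate",
                                  "concentration_nmol_L"))
}

#' CV-profile CSV
#'
#' Columns `nominal_nmol_L, replicate, measured_nmol_L`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_cv_profile <- function(path) {
  read_assay_csv(path, required = c("nominal_nmol_L", "replicate",
                                    "measured_nmol_L"),
                 numeric_cols = c("nominal_nmol_L", "replicate",
                                  "measured_nmol_L"))
}

#' Method-comparison CSV
#'
#' Columns `sample_id, reference_nmol_L, candidate_nmol_L`.
#'
#' @param path File path.
#' @return Data frame with columns `reference`, `candidate` ready for
#'   [method_comparison()] (plus `sample_id`).
#' @export
read_comparison_pairs <- function(path) {
  df <- read_assay_csv(path, required = c("sample_id", "reference_nmol_L",
                                          "candidate_nmol_L"),
                       numeric_cols = c("reference_nmol_L",
                                        "candidate_nmol_L"))
  data.frame(sample_id = df$sample_id, reference = df$reference_nmol_L,
             candidate = df$candidate_nmol_L, stringsAsFactors = FALSE)
}

# Short stable digest of an arbitrary R object: FNV-1a over its deparsed
# form, carried in doubles (h exceeds the 32-bit signed range, so the
# byte-xor is done on the low byte explicitly).
config_digest <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
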