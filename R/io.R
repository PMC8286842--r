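# Delimited-text readers and writers.  All files are UTF-8 CSV with
# '#key=value' metadata lines before the header; column names carry their
# units (conc_A_uM, potential_mV, ...) and are validated, never guessed.

read_csv_with_meta <- function(path) {
  if (!file.exists(path)) {
    nk_stop(sprintf("file not found: %s", path), "nitrokin_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(trimws(lines), "#")
  meta <- list()
  for (m in sub("^\\s*#", "", lines[is_meta])) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 1L) {
    nk_stop(sprintf("no data rows in %s", path), "nitrokin_io_error")
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(data = df, meta = meta, n_meta = sum(is_meta))
}

write_csv_with_meta <- function(df, path, metadata = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("#%s=%s", k, metadata[[k]]), con)
  }
  # full-precision formatting so write-then-read round trips preserve values
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

require_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    nk_stop(sprintf("%s: missing required column(s): %s", path,
                    paste(miss, collapse = ", ")), "nitrokin_schema_error")
  }
}

#' Read and write initial-rate tables
#'
#' Rate tables are CSV files with unit-suffixed columns `conc_A_uM`,
#' `conc_B_uM`, `conc_E_uM`, `rate_uM_per_s`, optionally `conc_I_uM`
#' (taken as 0 when absent) and `label`, preceded by any number of
#' `#key=value` metadata lines.  Malformed rows (negative concentrations,
#' non-finite rates) are reported with their line numbers.
#'
#' @param path File path.
#' @return `read_rate_table()`: data frame of observations with internal
#'   column names (`conc_A`, ..., `rate`) and a `metadata` attribute.
#' @export
read_rate_table <- function(path) {
  parsed <- read_csv_with_meta(path)
  df <- parsed$data
  require_columns(df, c("conc_A_uM", "conc_B_uM", "conc_E_uM",
                        "rate_uM_per_s"), path)
  out <- data.frame(conc_A = as.numeric(df$conc_A_uM),
                    conc_B = as.numeric(df$conc_B_uM),
                    conc_I = if ("conc_I_uM" %in% names(df))
                      as.numeric(df$conc_I_uM) else 0,
                    conc_E = as.numeric(df$conc_E_uM),
                    rate = as.numeric(df$rate_uM_per_s),
                    label = if ("label" %in% names(df))
                      as.character(df$label) else NA_character_,
                    stringsAsFactors = FALSE)
  bad <- which(out$conc_A < 0 | out$conc_B < 0 | out$conc_I < 0 |
                 !(out$conc_E > 0) | !is.finite(out$rate) |
                 is.na(out$conc_A) | is.na(out$conc_B))
  if (length(bad)) {
    nk_stop(sprintf("%s: invalid row(s) at data line(s) %s (negative or missing concentration, non-positive enzyme, or non-finite rate)",
                    path, paste(bad, collapse = ", ")),
            "nitrokin_validation_error")
  }
  attr(out, "metadata") <- parsed$meta
  out
}

#' @rdname read_rate_table
#' @param observations Data frame of observations (internal column names).
#' @param metadata Named list written as `#key=value` provenance lines.
#' @export
write_rate_table <- function(observations, path, metadata = list()) {
  df <- data.frame(conc_A_uM = observations$conc_A,
                   conc_B_uM = observations$conc_B,
                   conc_I_uM = observations$conc_I %||% 0,
                   conc_E_uM = observations$conc_E,
                   rate_uM_per_s = observations$rate,
                   label = observations$label %||% NA_character_,
                   stringsAsFactors = FALSE)
  prov <- attr(observations, "provenance")
  if (!is.null(prov) && is.null(metadata$provenance)) {
    metadata$provenance <- jsonlite::toJSON(prov, auto_unbox = TRUE,
                                            digits = NA)
  }
  write_csv_with_meta(df, path, metadata)
}

#' Read and write titration tables
#'
#' Titration tables are CSV files with columns `potential_mV` and
#' `absorbance`, optional `cycle` and `replicate`, and `#key=value`
#' metadata lines (wavelength, reference electrode, provenance).
#' Potentials are stored vs NHE; any electrode-reference conversion is an
#' explicit option here, never implicit.
#'
#' @param path File path.
#' @param reference_offset_mV Added to every potential on reading (e.g. an
#'   Ag/AgCl-to-NHE offset); default 0.
#' @return `read_titration_table()`: data frame with columns `potential`,
#'   `absorbance`, `cycle`, `replicate` and a `metadata` attribute.
#' @export
read_titration_table <- function(path, reference_offset_mV = 0) {
  parsed <- read_csv_with_meta(path)
  df <- parsed$data
  require_columns(df, c("potential_mV", "absorbance"), path)
  out <- data.frame(potential = as.numeric(df$potential_mV) +
                      reference_offset_mV,
                    absorbance = as.numeric(df$absorbance),
                    cycle = if ("cycle" %in% names(df))
                      as.character(df$cycle) else "cycle1",
                    replicate = if ("replicate" %in% names(df))
                      df$replicate else 1L,
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$potential) | !is.finite(out$absorbance) |
                 out$absorbance < 0)
  if (length(bad)) {
    nk_stop(sprintf("%s: invalid row(s) at data line(s) %s", path,
                    paste(bad, collapse = ", ")),
            "nitrokin_validation_error")
  }
  attr(out, "metadata") <- parsed$meta
  out
}

#' @rdname read_titration_table
#' @param points Data frame of titration points (internal column names).
#' @param metadata Named list written as `#key=value` lines.
#' @export
write_titration_table <- function(points, path, metadata = list()) {
  df <- data.frame(potential_mV = points$potential,
                   absorbance = points$absorbance,
                   cycle = points$cycle %||% "cycle1",
                   replicate = points$replicate %||% 1L,
                   stringsAsFactors = FALSE)
  prov <- attr(points, "provenance")
  if (!is.null(prov) && is.null(metadata$provenance)) {
    metadata$provenance <- jsonlite::toJSON(prov, auto_unbox = TRUE,
                                            digits = NA)
  }
  write_csv_with_meta(df, path, metadata)
}

#' Read and write assay traces
#'
#' Traces are CSV files with columns `time_s` and `absorbance`; the
#' wavelength and path length travel in `#wavelength_nm=` and
#' `#path_length_cm=` metadata lines.
#'
#' @param path File path.
#' @return `read_trace()`: an [assay_trace()].
#' @export
read_trace <- function(path) {
  parsed <- read_csv_with_meta(path)
  df <- parsed$data
  require_columns(df, c("time_s", "absorbance"), path)
  assay_trace(as.numeric(df$time_s), as.numeric(df$absorbance),
              wavelength_nm = as.numeric(parsed$meta$wavelength_nm %||%
                                           NA_real_),
              path_length_cm = as.numeric(parsed$meta$path_length_cm %||% 1))
}

#' @rdname read_trace
#' @param trace An [assay_trace()].
#' @param metadata Extra `#key=value` lines.
#' @export
write_trace <- function(trace, path, metadata = list()) {
  stopifnot(inherits(trace, "assay_trace"))
  metadata$wavelength_nm <- metadata$wavelength_nm %||% trace$wavelength_nm
  metadata$path_length_cm <- metadata$path_length_cm %||%
    trace$path_length_cm
  write_csv_with_meta(data.frame(time_s = trace$times,
                                 absorbance = trace$absorbances),
                      path, metadata)
}
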