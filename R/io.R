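# CSV persistence for the five linked tables (RFC-4180, UTF-8, ISO-8601
# dates), with validating reads that cite file, line and field on error.

.TABLE_SCHEMAS <- list(
  patients = list(
    file = "patients.csv",
    cols = c(patient_id = "character", sex = "character",
             birth_date = "date", bmi = "numeric",
             seifa_percentile = "integer"),
    optional = c("bmi", "seifa_percentile")),
  encounters = list(
    file = "encounters.csv",
    cols = c(patient_id = "character", encounter_date = "date",
             reason_text = "character"),
    optional = character(0)),
  pathology = list(
    file = "pathology.csv",
    cols = c(patient_id = "character", result_date = "date",
             analyte = "character", value = "numeric", units = "character"),
    optional = character(0)),
  prescriptions = list(
    file = "prescriptions.csv",
    cols = c(patient_id = "character", script_date = "date",
             medication_name = "character"),
    optional = character(0)),
  registry = list(
    file = "registry.csv",
    cols = c(patient_id = "character", diagnosis_date = "date",
             icd10_code = "character"),
    optional = character(0))
)

#' Write linked cohort tables to a directory of CSV files
#'
#' One file per table (`patients.csv`, `encounters.csv`, `pathology.csv`,
#' `prescriptions.csv`, `registry.csv`), UTF-8, ISO-8601 dates, empty
#' string for missing optional values. [read_tables()] round-trips the
#' result exactly, including missingness.
#'
#' @param tables A `pc_tables` list (see [generate_cohort_data()]).
#' @param directory Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_tables <- function(tables, directory) {
  stopifnot(all(names(.TABLE_SCHEMAS) %in% names(tables)))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(.TABLE_SCHEMAS)) {
    sch <- .TABLE_SCHEMAS[[nm]]
    df <- tables[[nm]][, names(sch$cols), drop = FALSE]
    for (cn in names(sch$cols)) {
      if (sch$cols[[cn]] == "date") df[[cn]] <- format(df[[cn]], "%Y-%m-%d")
    }
    utils::write.csv(df, file.path(directory, sch$file), row.names = FALSE,
                     na = "", quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(directory)
}

#' Read linked cohort tables from a directory of CSV files
#'
#' Validates types row by row: a malformed date or number raises an error
#' naming the file, line and field. Missing optional fields read back as
#' `NA`; required fields must be present and non-empty.
#'
#' @param directory Directory written by [write_tables()].
#' @return A `pc_tables` list.
#' @export
read_tables <- function(directory) {
  out <- list()
  for (nm in names(.TABLE_SCHEMAS)) {
    sch <- .TABLE_SCHEMAS[[nm]]
    path <- file.path(directory, sch$file)
    if (!file.exists(path)) {
      stop(sprintf("missing table file: %s", path), call. = FALSE)
    }
    raw <- utils::read.csv(path, colClasses = "character",
                           fileEncoding = "UTF-8", check.names = FALSE)
    missing_cols <- setdiff(names(sch$cols), names(raw))
    if (length(missing_cols) > 0) {
      stop(sprintf("%s: missing column(s): %s", sch$file,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    df <- raw[, names(sch$cols), drop = FALSE]
    for (cn in names(sch$cols)) {
      df[[cn]] <- parse_column(df[[cn]], sch$cols[[cn]], sch$file, cn,
                               optional = cn %in% sch$optional)
    }
    rownames(df) <- NULL
    out[[nm]] <- df
  }
  structure(out, class = "pc_tables")
}

parse_column <- function(x, type, file, field, optional) {
  blank <- !nzchar(x)
  if (any(blank) && !optional) {
    stop(sprintf("%s line %d: required field '%s' is empty",
                 file, which(blank)[1] + 1L, field), call. = FALSE)
  }
  if (type == "character") return(ifelse(blank, NA_character_, x))
  parsed <- switch(type,
    date = as.Date(x, format = "%Y-%m-%d", optional = TRUE),
    numeric = suppressWarnings(as.numeric(x)),
    integer = suppressWarnings(as.integer(x))
  )
  bad <- !blank & is.na(parsed)
  if (any(bad)) {
    stop(sprintf("%s line %d: field '%s' has malformed %s value '%s'",
                 file, which(bad)[1] + 1L, field, type, x[bad][1]),
         call. = FALSE)
  }
  if (type == "date") parsed[blank] <- NA
  parsed
}
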