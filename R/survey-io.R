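#' Survey file schema
#'
#' Column names and types of the delimited-text survey format. Missing
#' values are encoded as empty fields; `.true_*` generator-truth columns are
#' never written.
#'
#' @return a tibble with columns `column` and `type` (`"character"` or
#'   `"integer"`).
#' @export
survey_schema <- function() {
  meta <- service_meta()
  tibble(
    column = c("id", "wave", "sex", "age_band", "income_band", "occupation",
               "education", "household_size", "insurance", "ghq12", "sph",
               "chronic_count", "group_id",
               meta$count_col, meta$private_col,
               meta$delayed_col[!is.na(meta$delayed_col)], medicine_cols()),
    type = c("character", "integer", "character", "character", "integer",
             "character", "character", "integer", "integer", "integer",
             "character", "integer", "character",
             rep("integer", 4), rep("integer", 4), rep("integer", 2),
             rep("integer", 22))
  )
}

#' Write / read survey microdata as delimited text
#'
#' `write_survey()` writes a UTF-8 CSV with a header row, missing values as
#' empty fields, dropping any `.true_*` columns. `read_survey()` reads it
#' back with the schema's column types and validates the result with
#' [validate_survey()]; the round trip is the identity on the schema
#' columns.
#'
#' @param data survey records.
#' @param path file path.
#' @return `read_survey()`: a validated tibble.
#' @export
write_survey <- function(data, path) {
  validate_survey(data)
  keep <- survey_schema()$column
  readr::write_csv(data[, keep], path, na = "")
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  sch <- survey_schema()
  cts <- paste(ifelse(sch$type == "integer", "i", "c"), collapse = "")
  d <- readr::read_csv(path, col_types = cts, na = "")
  if (!identical(names(d), sch$column)) {
    unknown <- setdiff(names(d), sch$column)
    missing <- setdiff(sch$column, names(d))
    abort(paste0("schema mismatch.",
                 if (length(unknown)) paste0(" Unknown column(s): ",
                                             paste(unknown, collapse = ", "), "."),
                 if (length(missing)) paste0(" Missing column(s): ",
                                             paste(missing, collapse = ", "), ".")),
          class = "equicare_schema_error")
  }
  validate_survey(d)
  d
}

schema_abort <- function(column, rows, what) {
  abort(sprintf("schema violation in column '%s' (row %s%s): %s",
                column, rows[1],
                if (length(rows) > 1) sprintf(" and %d more", length(rows) - 1) else "",
                what),
        class = "equicare_schema_error")
}

#' Validate survey records against the schema invariants
#'
#' Checks category sets, ranges (GHQ-12 in 0-12, income band within the
#' wave's dialect, counts non-negative), binary flags, and the linkage
#' invariants: the last-contact ownership flag and the delayed-contact
#' indicator are missing if and only if the corresponding reported count is
#' zero. Violations raise a schema error naming the column and first
#' offending row.
#'
#' @param data survey records.
#' @return `data`, invisibly.
#' @export
validate_survey <- function(data) {
  sch <- survey_schema()
  missing <- setdiff(sch$column, names(data))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "equicare_schema_error")
  }
  unknown <- setdiff(names(data), c(sch$column, grep("^\\.true_", names(data), value = TRUE)))
  if (length(unknown)) {
    abort(paste0("unknown column(s): ", paste(unknown, collapse = ", ")),
          class = "equicare_schema_error")
  }
  chk_set <- function(col, set) {
    bad <- which(!is.na(data[[col]]) & !(data[[col]] %in% set))
    if (length(bad)) schema_abort(col, bad, paste0("value outside {",
                                                   paste(set, collapse = ", "), "}"))
  }
  chk_set("wave", c(2006L, 2011L))
  chk_set("sex", c("male", "female"))
  chk_set("age_band", age_levels())
  chk_set("occupation", occupation_levels())
  chk_set("education", education_levels())
  chk_set("sph", sph_levels())
  chk_set("insurance", 0:1)
  bad <- which(!is.na(data$ghq12) & (data$ghq12 < 0 | data$ghq12 > 12))
  if (length(bad)) schema_abort("ghq12", bad, "must lie in 0-12")
  kmax <- ifelse(data$wave == 2006, 8L, 10L)
  bad <- which(!is.na(data$income_band) &
                 (data$income_band < 1 | data$income_band > kmax))
  if (length(bad)) schema_abort("income_band", bad, "outside the wave's dialect range")
  for (col in c("household_size", "chronic_count")) {
    lo <- if (col == "household_size") 1 else 0
    bad <- which(!is.na(data[[col]]) & data[[col]] < lo)
    if (length(bad)) schema_abort(col, bad, sprintf("must be >= %d", lo))
  }
  meta <- service_meta()
  for (i in seq_len(nrow(meta))) {
    cnt <- data[[meta$count_col[i]]]
    bad <- which(is.na(cnt) | cnt < 0)
    if (length(bad)) schema_abort(meta$count_col[i], bad, "counts must be >= 0 and complete")
    for (col in c(meta$private_col[i], meta$delayed_col[i])) {
      if (is.na(col)) next
      chk_set(col, 0:1)
      bad <- which(cnt == 0 & !is.na(data[[col]]))
      if (length(bad)) schema_abort(col, bad, "set although the reported count is zero")
      bad <- which(cnt > 0 & is.na(data[[col]]))
      if (length(bad)) schema_abort(col, bad, "missing although the reported count is positive")
    }
  }
  for (col in medicine_cols()) chk_set(col, 0:1)
  invisible(data)
}
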