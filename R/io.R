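# Cohort CSV round-trip with a versioned schema header. Dates are
# ISO-8601, missing values are empty fields.

cohort_schema_header <- "# bpwmh cohort schema v1"

#' Write / read a visit table as CSV
#'
#' The file starts with a versioned schema comment line
#' (`# bpwmh cohort schema v1`) so downstream readers can refuse
#' unrecognized layouts; dates are ISO-8601 and missing values are empty
#' fields. `read_cohort_csv()` restores column types (dates, logicals)
#' and errors on a missing or unknown schema line.
#'
#' @param visits Visit table in the [generate_cohort()] schema.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the visit tibble.
#' @export
write_cohort_csv <- function(visits, path) {
  writeLines(cohort_schema_header, path)
  readr::write_csv(visits, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, cohort_schema_header)) {
    abort(sprintf("Unrecognized cohort file: expected header '%s'.",
                  cohort_schema_header))
  }
  readr::read_csv(
    path, skip = 1, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      visit = readr::col_character(),
      visit_date = readr::col_date(),
      sex = readr::col_character(),
      smoking = readr::col_character(),
      centre = readr::col_character(),
      diabetes = readr::col_logical(),
      antihypertensive = readr::col_logical(),
      exclusion_flag = readr::col_logical(),
      .default = readr::col_double()
    )
  )
}
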