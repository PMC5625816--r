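#' Read a clinical cohort table from CSV
#'
#' Expects a header with columns `patient_id, age, sex, stage, histology,
#' treatment_type, chemotherapy, ild, smoking_pack_years, bmi, rp_grade`.
#' Validation rejects duplicate patient ids, RP grades outside 0-5, stages
#' outside 1-4 and non-0/1 binary flags, naming the offending row and column.
#'
#' @param path CSV file path.
#' @return a [CohortTable-class].
#' @export
readCohortTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohortRequiredCols, names(df))
  if (length(missing))
    stop(sprintf("cohort table %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!(df$rp_grade %in% 0:5))
  if (length(bad))
    stop(sprintf("cohort table %s: column 'rp_grade' out of range {0..5} in row %d (value %s)",
                 path, bad[1], df$rp_grade[bad[1]]), call. = FALSE)
  for (col in c("chemotherapy", "ild")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("cohort table %s: column '%s' must be 0/1 in row %d (value %s)",
                   path, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id))
    stop(sprintf("cohort table %s: duplicate patient_id '%s'", path,
                 df$patient_id[duplicated(df$patient_id)][1]), call. = FALSE)
  cohortTable(df, provenance = path)
}

#' Write a cohort table to CSV
#' @param cohort a [CohortTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  utils::write.csv(records(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Derive a binary pneumonitis endpoint from CTCAE grades
#'
#' The primary endpoint of the analysis is symptomatic radiation pneumonitis,
#' grade >= 2; the secondary endpoint is grade >= 3.
#'
#' @param rpGrade integer vector of CTCAE RP grades (0-5).
#' @param cutoff endpoint grade cutoff, 2 or 3.
#' @return logical vector, `TRUE` where `rpGrade >= cutoff`.
#' @examples
#' deriveEndpoint(c(0, 1, 2, 3), cutoff = 2)
#' @export
deriveEndpoint <- function(rpGrade, cutoff = 2) {
  if (!(cutoff %in% c(2, 3))) stop("cutoff must be 2 or 3", call. = FALSE)
  if (any(!(rpGrade %in% 0:5)))
    stop("rp_grade values must lie in {0..5}", call. = FALSE)
  rpGrade >= cutoff
}
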