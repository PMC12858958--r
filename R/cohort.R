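#' Read / write cohort tables as tab-separated text
#'
#' A cohort table holds one row per individual with baseline age,
#' subgroup label, standardized PGS, the 5-year incident-case flag and
#' design columns (`prevalent_case`, `screening_history`,
#' `subcohort_member`, `design_weight`). Files have a one-line header and
#' encode missing values as `NA`; gzip is read transparently.
#'
#' @param path File path.
#' @return `read_cohort_table()` returns a `"cohort_table"` data frame;
#'   `write_cohort_table()` returns `path` invisibly.
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample_id", "age_at_baseline", "subgroup", "incident_case_5y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"design_weight" %in% names(d)) d$design_weight <- 1
  if (!"prevalent_case" %in% names(d)) d$prevalent_case <- FALSE
  validate_cohort_table(d)
}

#' @rdname read_cohort_table
#' @param cohort A `"cohort_table"`.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate cohort-table invariants
#'
#' Checks that design weights are positive and that no record is flagged
#' both prevalent and incident (the incident analysis set requires the
#' two to be disjoint).
#'
#' @param cohort A data frame with cohort columns.
#' @return The validated `"cohort_table"`, invisibly classed.
#' @export
validate_cohort_table <- function(cohort) {
  if ("design_weight" %in% names(cohort) &&
      any(cohort$design_weight <= 0, na.rm = TRUE))
    stop("design_weight must be positive", call. = FALSE)
  if (all(c("incident_case_5y", "prevalent_case") %in% names(cohort)) &&
      any(cohort$incident_case_5y & cohort$prevalent_case, na.rm = TRUE))
    stop("a record cannot be both an incident and a prevalent case",
         call. = FALSE)
  if (!inherits(cohort, "cohort_table"))
    class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
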