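#' Reference DOC cohort table
#'
#' The bundled cohort of 21 patients with prolonged disorders of
#' consciousness treated with a 10-session course of HD-tDCS over the left
#' dorsolateral prefrontal cortex: demographics, etiology, days since onset,
#' and CRS-R totals with behavioral diagnoses at baseline (T0), after one
#' session (T1), and after the full course (T2). Twelve patients improved
#' their CRS-R total from T0 to T2 (the responsive, RE, group); nine did not
#' (N-RE).
#'
#' @return data.frame with 21 rows and columns `patient_id`, `group`
#'   (RE/N-RE), `sex`, `age` (years), `etiology`, `course_days`, `crsr_t0`,
#'   `diagnosis_t0`, `crsr_t1`, `diagnosis_t1`, `crsr_t2`, `diagnosis_t2`,
#'   `followup_3mo`. CRS-R totals lie in 0..23.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_doc.csv", package = "eegmicrostates")
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(nrow(df) == 21, all(df$crsr_t0 >= 0 & df$crsr_t0 <= 23),
            all(df$crsr_t2 >= 0 & df$crsr_t2 <= 23))
  df
}

#' Classify patients as responsive or non-responsive
#'
#' A patient is responsive (RE) iff the CRS-R total improved over the
#' stimulation course, i.e. `crsr_t2 > crsr_t0`; otherwise non-responsive
#' (N-RE).
#'
#' @param cohort data.frame with integer columns `crsr_t0` and `crsr_t2`.
#' @return character vector of `"RE"` / `"N-RE"`, one per row.
#' @export
classify_responders <- function(cohort) {
  if (is.null(cohort$crsr_t0) || is.null(cohort$crsr_t2) ||
      anyNA(cohort$crsr_t0) || anyNA(cohort$crsr_t2)) {
    stop("cohort must provide complete crsr_t0 and crsr_t2 columns")
  }
  ifelse(cohort$crsr_t2 > cohort$crsr_t0, "RE", "N-RE")
}
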