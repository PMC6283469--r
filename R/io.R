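#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `patients.csv` (one row per patient) and
#' `series.csv` (long format: `patient_id`, `week`, `variable`, `value`,
#' `observed`) into `dir`; `read_cohort()` reads them back. Files are UTF-8,
#' comma-separated with a header row.
#'
#' @param cohort A `vlab_cohort`.
#' @param dir Directory (created if missing).
#' @return `write_cohort()` returns the directory invisibly; `read_cohort()`
#'   returns a `vlab_cohort` (without a spec).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vlab_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  long <- tidyr::pivot_longer(
    cohort$series,
    cols = c("pain", "prsi", "dose_mg", "calm", "energy", "sad"),
    names_to = "variable", values_to = "value"
  )
  long <- long[, c("patient_id", "week", "variable", "value", "observed")]
  utils::write.csv(long, file.path(dir, "series.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- as_tibble(utils::read.csv(file.path(dir, "patients.csv"),
                                        stringsAsFactors = FALSE))
  long <- as_tibble(utils::read.csv(file.path(dir, "series.csv"),
                                    stringsAsFactors = FALSE))
  series <- tidyr::pivot_wider(long, names_from = "variable",
                               values_from = "value")
  series <- series[, c("patient_id", "week", "pain", "prsi", "dose_mg",
                       "calm", "energy", "sad", "observed")]
  series <- arrange(series, .data$patient_id, .data$week)
  structure(list(patients = patients, series = series, spec = NULL),
            class = "vlab_cohort")
}
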