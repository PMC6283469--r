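#' The nine baseline clustering variables
#'
#' Gender, age, insulin use, BMI, depression history, pregabalin monotherapy,
#' prior gabapentin, baseline pain score and baseline PRSI score.
#'
#' @return Character vector of column names.
#' @export
clustering_variables <- function() {
  c("gender", "age_years", "insulin", "bmi_kg_m2", "depression_history",
    "pregabalin_monotherapy", "prior_gabapentin", "baseline_pain",
    "baseline_prsi")
}

gower_numeric_vars <- function(records, variables) {
  variables[vapply(records[variables],
                   function(x) is.numeric(x) && !is.logical(x), logical(1))]
}

#' Ranges of the numeric clustering variables over a cohort
#'
#' @param records Patient tibble.
#' @param variables Variables considered (default the nine clustering
#'   variables).
#' @return Named numeric vector `max - min` for each numeric variable.
#' @export
gower_ranges <- function(records, variables = clustering_variables()) {
  num <- gower_numeric_vars(records, variables)
  vapply(records[num], function(x) diff(range(x, na.rm = TRUE)), numeric(1))
}

#' Gower dissimilarity between mixed-type patient records
#'
#' The Gower distance is the mean over variables of per-variable
#' dissimilarities: `|a - b| / range` for numeric variables and a 0/1
#' mismatch indicator for dichotomous or categorical variables. It is
#' symmetric, lies in `[0, 1]`, and is 0 exactly when the two records agree
#' on every included variable. Numeric variables with zero range carry no
#' information and are excluded with a warning.
#'
#' `gower_distance()` compares two single records; `gower_matrix()` returns
#' the full pairwise matrix for a cohort (used by [cluster_patients()]).
#'
#' @param a,b One-row tibbles (or named lists) holding the variables.
#' @param records Patient tibble for the pairwise form.
#' @param variables Variables to compare.
#' @param ranges Named ranges for numeric variables (`max - min` over the
#'   cohort); computed from `records` when omitted in `gower_matrix()`.
#' @return A scalar in `[0, 1]`, or an `n x n` matrix.
#' @examples
#' r <- tibble::tibble(gender = c("F", "M"), age_years = c(50, 60))
#' gower_distance(r[1, ], r[2, ], c("gender", "age_years"),
#'                ranges = c(age_years = 40))
#' @export
gower_distance <- function(a, b, variables = clustering_variables(),
                           ranges = NULL) {
  a <- as.list(a); b <- as.list(b)
  contrib <- numeric(0)
  for (v in variables) {
    av <- a[[v]]; bv <- b[[v]]
    if (is.numeric(av) && !is.logical(av)) {
      r <- ranges[[v]]
      if (is.null(r)) abort(paste0("range required for numeric variable `", v, "`"))
      if (r <= 0) {
        warn(paste0("variable `", v, "` has zero range; excluded from Gower distance"))
        next
      }
      contrib[v] <- abs(av - bv) / r
    } else {
      contrib[v] <- as.numeric(!identical(as.character(av), as.character(bv)))
    }
  }
  if (!length(contrib)) abort("no usable variables for Gower distance")
  mean(contrib)
}

#' @rdname gower_distance
#' @export
gower_matrix <- function(records, variables = clustering_variables(),
                         ranges = NULL) {
  n <- nrow(records)
  num <- gower_numeric_vars(records, variables)
  if (is.null(ranges)) ranges <- gower_ranges(records, variables)
  acc <- matrix(0, n, n)
  used <- 0L
  for (v in variables) {
    if (v %in% num) {
      r <- ranges[[v]]
      if (is.na(r) || r <= 0) {
        warn(paste0("variable `", v,
                    "` has zero range; excluded from Gower distance"))
        next
      }
      x <- records[[v]]
      acc <- acc + abs(outer(x, x, "-")) / r
    } else {
      x <- as.character(records[[v]])
      acc <- acc + outer(x, x, "!=")
    }
    used <- used + 1L
  }
  if (used == 0L) abort("no usable variables for Gower distance")
  d <- acc / used
  dimnames(d) <- list(records$patient_id, records$patient_id)
  d
}
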