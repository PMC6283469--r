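#' Published per-cluster lagged pain regressions
#'
#' The six cluster-specific regression equations for weekly pain score that the
#' simulation engine and the synthetic-cohort generator use as the reference
#' data-generating process. Each model predicts pain at week `t` (0--10 NRS)
#' from, at most: pain one week earlier (`pain_lag1`), concurrent pain-related
#' sleep interference (`prsi_lag0`), PRSI three weeks earlier (`prsi_lag3`),
#' pregabalin dose three weeks earlier in mg/day (`dose_lag3`), an indicator
#' for the 75+ age cohort (`age_75plus`), and the baseline "calm and relaxed"
#' and "full of energy" general-feeling items coded 1 = always ... 6 = never
#' (`calm_baseline`, `energy_baseline`). The models have no intercept.
#'
#' @return A tibble with columns `cluster` (1--6), `term` and `estimate`.
#' @examples
#' reference_cluster_models()
#' @export
reference_cluster_models <- function() {
  mk <- function(cluster, ...) {
    co <- c(...)
    tibble(cluster = cluster, term = names(co), estimate = unname(co))
  }
  bind_rows(
    mk(1L, pain_lag1 = 0.6229, prsi_lag0 = 0.2461, dose_lag3 = 0.0002,
       calm_baseline = 0.0354),
    mk(2L, pain_lag1 = 0.7590, prsi_lag0 = 0.1417, prsi_lag3 = -0.0455,
       dose_lag3 = 0.0002, age_75plus = 0.1039, calm_baseline = 0.0557),
    mk(3L, pain_lag1 = 0.7605, prsi_lag0 = 0.2393, prsi_lag3 = -0.0707,
       dose_lag3 = 0.0002, energy_baseline = 0.0162),
    mk(4L, pain_lag1 = 0.6294, prsi_lag0 = 0.2146, dose_lag3 = 0.0003,
       calm_baseline = 0.0671, energy_baseline = 0.0043),
    mk(5L, pain_lag1 = 0.6415, prsi_lag0 = 0.2234, calm_baseline = 0.0150,
       energy_baseline = 0.0133),
    mk(6L, pain_lag1 = 0.6652, prsi_lag0 = 0.1945, calm_baseline = 0.0107,
       energy_baseline = 0.0449)
  )
}

#' Reference coefficient vector for one cluster
#'
#' @param cluster Cluster id, 1--6.
#' @return Named numeric vector of coefficients.
#' @export
reference_coefficients <- function(cluster) {
  m <- reference_cluster_models()
  m <- m[m$cluster == cluster, ]
  if (nrow(m) == 0) abort(paste0("no reference model for cluster ", cluster))
  setNames(m$estimate, m$term)
}

# Ordered levels shared across the package ------------------------------------

age_group_levels <- function() c("0-44", "45-64", "65-74", "75+")
bmi_group_levels <- function() c("normal", "overweight", "obese")
pain_category_levels <- function() c("moderate", "severe")
prsi_category_levels <- function() c("mild", "moderate", "severe")
duration_group_levels <- function() {
  c("0-5", ">5-10", ">10-15", ">15-20", ">20-25", ">25")
}
dose_levels <- function() c(75, 150, 300, 600)

#' Derive the categorical groupings used for coarsening and coverage
#'
#' Age groups follow the 0--44 / 45--64 / 65--74 / 75+ cohorts; BMI groups use
#' the WHO cut points (normal < 25, overweight 25 to < 30, obese >= 30);
#' baseline pain severity is moderate (4--6) vs severe (7--10); baseline PRSI
#' is mild (0--3), moderate (4--6) or severe (7--10). Severity boundaries are
#' right-open at the category upper edge, i.e. a score of exactly 7 is severe.
#'
#' @param age_years,bmi_kg_m2,pain,prsi Numeric vectors.
#' @return Character vector of group labels.
#' @name derive-groups
NULL

#' @rdname derive-groups
#' @export
age_group_of <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 44, 64, 74, Inf),
      labels = age_group_levels()) |> as.character()
}

#' @rdname derive-groups
#' @export
bmi_group_of <- function(bmi_kg_m2) {
  cut(bmi_kg_m2, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
      labels = bmi_group_levels()) |> as.character()
}

#' @rdname derive-groups
#' @export
pain_category_of <- function(pain) {
  out <- ifelse(pain < 4, NA_character_,
                ifelse(pain < 7, "moderate", "severe"))
  if (anyNA(out)) warn("pain scores below 4 fall outside the severity bins")
  out
}

#' @rdname derive-groups
#' @export
prsi_category_of <- function(prsi) {
  ifelse(prsi < 4, "mild", ifelse(prsi < 7, "moderate", "severe"))
}
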