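#' Three-point Lagrange quadratic interpolation
#'
#' Fills target weeks by evaluating the Lagrange quadratic through the three
#' observed `(week, value)` points nearest the target; ties in nearness are
#' broken toward earlier weeks (the window that would have been available
#' first). This is the classical second-order interpolation used to impute
#' visit schedules with gaps. Results are clipped to `clip` (the 0--10 NRS by
#' default); observed weeks are never altered.
#'
#' @param obs_weeks,obs_values Observed week indices and values (length >= 3).
#' @param target_weeks Weeks to fill; must lie within `[min(obs), max(obs)]`.
#' @param clip Length-2 bounds applied to interpolated values, or `NULL`.
#' @return Numeric vector of interpolated values, one per target week.
#' @examples
#' quadratic_interpolate(c(0, 1, 3, 6), c(6, 5, 3, 0), c(2, 4, 5))
#' @export
quadratic_interpolate <- function(obs_weeks, obs_values, target_weeks,
                                  clip = c(0, 10)) {
  keep <- !is.na(obs_values)
  obs_weeks <- obs_weeks[keep]; obs_values <- obs_values[keep]
  if (length(obs_weeks) < 3)
    abort("quadratic interpolation needs at least 3 observed points")
  if (any(target_weeks < min(obs_weeks) | target_weeks > max(obs_weeks)))
    abort("interpolation targets must lie inside the observed span (no extrapolation)")
  out <- vapply(target_weeks, function(t) {
    hit <- which(obs_weeks == t)
    if (length(hit)) return(obs_values[hit[1]])
    ord <- order(abs(obs_weeks - t), obs_weeks)[1:3]
    w <- obs_weeks[ord]; v <- obs_values[ord]
    # Lagrange basis evaluation at t
    sum(vapply(1:3, function(i) {
      o <- setdiff(1:3, i)
      v[i] * prod((t - w[o]) / (w[i] - w[o]))
    }, numeric(1)))
  }, numeric(1))
  if (!is.null(clip)) out <- pmin(clip[2], pmax(clip[1], out))
  out
}

#' Impute unobserved weeks of a weekly series table
#'
#' Applies [quadratic_interpolate()] per patient to the `pain`, `prsi` and
#' general-feeling columns of a long weekly series, filling the requested
#' target weeks where `observed` is `FALSE`. Feeling items are rounded back
#' to the 1--6 ordinal scale. Patients whose observed span does not cover a
#' target week, or with fewer than 3 observed values, raise an error naming
#' the patient.
#'
#' @param series Long series tibble as produced by [generate_cohort()].
#' @param target_weeks Integer weeks to fill (default the OS gaps 2, 4, 5).
#' @return The series with imputed values (observed flags unchanged).
#' @export
interpolate_weeks <- function(series, target_weeks = c(2L, 4L, 5L)) {
  fill_one <- function(df) {
    need <- df$week %in% target_weeks & !df$observed
    if (!any(need)) return(df)
    obs <- df$observed & !is.na(df$pain)
    for (col in c("pain", "prsi")) {
      df[[col]][need] <- quadratic_interpolate(
        df$week[obs], df[[col]][obs], df$week[need], clip = c(0, 10))
    }
    for (col in c("calm", "energy", "sad")) {
      v <- quadratic_interpolate(df$week[obs], df[[col]][obs],
                                 df$week[need], clip = c(1, 6))
      df[[col]][need] <- as.integer(round(v))
    }
    df
  }
  out <- series %>%
    group_by(.data$patient_id) %>%
    dplyr::group_modify(function(df, key) {
      tryCatch(fill_one(df), error = function(e) {
        abort(paste0("patient ", key$patient_id, ": ", conditionMessage(e)))
      })
    }) %>%
    ungroup()
  out[, names(series)]
}

#' Responder status at a horizon week
#'
#' A patient is a responder at threshold `tau` when the fractional reduction
#' from baseline, `(pain_0 - pain_t) / pain_0`, is at least `tau` at the
#' horizon week (the boundary counts as responding). The conventional
#' thresholds are 0.50 and the clinically meaningful 0.30.
#'
#' @param series Long weekly series (imputed as needed).
#' @param threshold Fractional reduction threshold in (0, 1].
#' @param horizon_week Integer week at which status is read, or `"final"` for
#'   each patient's last recorded week.
#' @return A tibble: `patient_id`, `threshold`, `horizon_week`, `pct_change`,
#'   `is_responder`.
#' @examples
#' s <- tibble::tibble(patient_id = "a", week = c(0, 6), pain = c(8, 4),
#'                     observed = TRUE)
#' derive_responder(s, 0.5, 6)
#' @export
derive_responder <- function(series, threshold = 0.5, horizon_week = 6L) {
  stopifnot(threshold > 0, threshold <= 1)
  base <- series %>% filter(.data$week == 0) %>%
    select("patient_id", pain0 = "pain")
  if (any(is.na(base$pain0)) || any(base$pain0 <= 0))
    abort("baseline pain must be present and positive for every patient")
  if (identical(horizon_week, "final")) {
    hor <- series %>% filter(!is.na(.data$pain)) %>%
      group_by(.data$patient_id) %>%
      summarise(horizon_week = max(.data$week),
                pain_t = .data$pain[which.max(.data$week)], .groups = "drop")
  } else {
    hor <- series %>% filter(.data$week == horizon_week) %>%
      mutate(horizon_week = as.integer(horizon_week)) %>%
      select("patient_id", "horizon_week", pain_t = "pain")
    missing <- setdiff(base$patient_id, hor$patient_id[!is.na(hor$pain_t)])
    if (length(missing))
      abort(paste0("missing pain at horizon week ", horizon_week, " for: ",
                   paste(head(missing, 5), collapse = ", ")))
  }
  left_join(base, hor, by = "patient_id") %>%
    mutate(threshold = threshold,
           pct_change = (.data$pain0 - .data$pain_t) / .data$pain0,
           is_responder = .data$pct_change >= threshold) %>%
    select("patient_id", "threshold", "horizon_week", "pct_change",
           "is_responder")
}
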