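#' Trajectory monotonicity
#'
#' The mean step sign of a trajectory: `(1/T) * sum_t sign(p[t+1] - p[t])`,
#' with `sign(0) = 0`. It lies in `[-1, 1]`; +1 is a strictly increasing
#' (worsening) pain trajectory, -1 strictly decreasing, 0 a trajectory with
#' balanced up and down moves. Only the step directions matter, so the
#' statistic is invariant to positive affine rescaling of the scores and
#' antisymmetric under time reversal.
#'
#' @param trajectory Numeric vector of scores at consecutive weeks
#'   (length >= 2).
#' @return A number in `[-1, 1]`.
#' @examples
#' trajectory_monotonicity(c(6, 5, 6, 5, 6, 5, 4))
#' @export
trajectory_monotonicity <- function(trajectory) {
  trajectory <- trajectory[!is.na(trajectory)]
  if (length(trajectory) < 2)
    abort("monotonicity needs at least two trajectory points")
  mean(sign(diff(trajectory)))
}

#' Classify a monotonicity value with the +/-0.2 thresholds
#'
#' Three-way classification: `below_negative` (`x < -0.2`), `between`
#' (`-0.2 <= x <= 0.2`, boundaries inclusive) and `above_positive`
#' (`x > 0.2`). The thresholds are the values that produce balanced
#' decreased/maintained/increased groups in long-duration trial data.
#'
#' @param value Monotonicity value(s) in `[-1, 1]`.
#' @param thresholds Length-2 `c(negative, positive)` cut points.
#' @return Character vector of categories.
#' @export
classify_monotonicity <- function(value, thresholds = c(-0.2, 0.2)) {
  stopifnot(all(value >= -1 & value <= 1))
  ifelse(value < thresholds[1], "below_negative",
         ifelse(value > thresholds[2], "above_positive", "between"))
}

#' Build the long-duration reference pool for extrapolation
#'
#' For each 12/13-week patient: median-free observed week-6 pain, the week
#' 0--6 monotonicity, and the week-6 to end-of-study responder transition at
#' the 50% threshold (`increased_pain` = responder who lost response,
#' `decreased_pain` = non-responder who gained it, `maintained` otherwise).
#'
#' @param patients Patient tibble (only `duration_weeks > 6` rows are used).
#' @param series Their weekly series.
#' @param threshold Responder threshold (default 0.5).
#' @return Tibble: `patient_id`, `pain_week6`, `monotonicity`, `status6`,
#'   `status_end`, `transition`.
#' @export
long_duration_pool <- function(patients, series, threshold = 0.5) {
  long <- patients[patients$duration_weeks > 6, ]
  if (!nrow(long)) abort("no long-duration patients in the pool")
  s <- series[series$patient_id %in% long$patient_id, ]
  r6 <- derive_responder(s, threshold, 6L)
  rend <- derive_responder(s, threshold, "final")
  mono <- s %>% filter(.data$week <= 6) %>% arrange(.data$week) %>%
    group_by(.data$patient_id) %>%
    summarise(monotonicity = trajectory_monotonicity(.data$pain),
              pain_week6 = .data$pain[.data$week == 6], .groups = "drop")
  out <- mono %>%
    left_join(select(r6, "patient_id", status6 = "is_responder"),
              by = "patient_id") %>%
    left_join(select(rend, "patient_id", status_end = "is_responder"),
              by = "patient_id") %>%
    mutate(transition = ifelse(.data$status6 & !.data$status_end,
                               "increased_pain",
                               ifelse(!.data$status6 & .data$status_end,
                                      "decreased_pain", "maintained")))
  out
}

#' Extrapolate responder status beyond week 6
#'
#' Finds the `k` long-duration trial patients nearest the simulated novel
#' patient in the (median week-6 pain, cloud monotonicity) plane (Euclidean
#' distance on the raw scales), labels each neighbour by its observed week-6
#' to week-12/13 responder transition, and predicts the majority label. A
#' majority tie is resolved to `maintained` (the most common outcome) and
#' flagged.
#'
#' @param sim A `vlab_sim`, or a list with `median_final_pain` and
#'   `cloud_monotonicity`.
#' @param pool Long-duration reference pool from [long_duration_pool()].
#' @param k Neighbours to consult; default `round(sqrt(nrow(pool)))`.
#' @param thresholds Monotonicity classification thresholds.
#' @return A `vlab_extrapolation`: monotonicity `value` and `category`,
#'   `horizon_prediction` (`decreased_pain` / `maintained` /
#'   `increased_pain`), the neighbour histogram and the tie flag.
#' @export
extrapolate_status <- function(sim, pool, k = NULL,
                               thresholds = c(-0.2, 0.2)) {
  if (!nrow(pool)) abort("long-duration pool is empty")
  if (is.null(k)) k <- k_rule(nrow(pool))
  k <- min(k, nrow(pool))
  d <- sqrt((pool$pain_week6 - sim$median_final_pain)^2 +
              (pool$monotonicity - sim$cloud_monotonicity)^2)
  nb <- pool[order(d, pool$patient_id)[seq_len(k)], ]
  cats <- c("decreased_pain", "maintained", "increased_pain")
  hist <- table(factor(nb$transition, levels = cats))
  top <- max(hist)
  winners <- names(hist)[hist == top]
  tie <- length(winners) > 1
  prediction <- if (tie) "maintained" else winners
  structure(
    list(value = sim$cloud_monotonicity,
         category = classify_monotonicity(sim$cloud_monotonicity,
                                          thresholds),
         horizon_prediction = prediction, tie = tie,
         neighbor_histogram = setNames(as.integer(hist), names(hist)),
         k = k),
    class = "vlab_extrapolation"
  )
}

#' @export
print.vlab_extrapolation <- function(x, ...) {
  cat("<vlab_extrapolation> monotonicity ", sprintf("%.3f", x$value),
      " (", x$category, ") -> ", x$horizon_prediction,
      if (x$tie) " [tie]", "\n  neighbours: ",
      paste(names(x$neighbor_histogram), x$neighbor_histogram,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn extrapolate_status Neighbour transition histogram.
#' @param object A `vlab_extrapolation`.
#' @export
#' @method autoplot vlab_extrapolation
autoplot.vlab_extrapolation <- function(object, ...) {
  df <- tibble(transition = names(object$neighbor_histogram),
               n = as.integer(object$neighbor_histogram))
  ggplot2::ggplot(df, ggplot2::aes(.data$transition, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "observed week 6 -> 12/13 transition",
                  y = "nearest neighbours")
}

#' Evaluate extrapolation predictions
#'
#' Per-category accuracy (the fraction of each true category predicted
#' correctly) and one-vs-rest ROC curves obtained by varying the
#' neighbour-vote fraction threshold. Categories absent from the truths are
#' reported as missing.
#'
#' @param predictions Character vector of predicted categories.
#' @param truths Character vector of true categories (same length).
#' @param vote_fractions Optional numeric matrix (rows = cases, columns =
#'   the three categories) of neighbour vote fractions; required for ROC.
#' @return List with `accuracy` (tibble `category`, `n`, `accuracy`) and
#'   `roc` (tibble `category`, `threshold`, `tpr`, `fpr`, plus trapezoidal
#'   `auc`), or `roc = NULL` without vote fractions.
#' @export
evaluate_extrapolation <- function(predictions, truths,
                                   vote_fractions = NULL) {
  if (length(predictions) != length(truths))
    abort("`predictions` and `truths` must have equal length")
  cats <- c("decreased_pain", "maintained", "increased_pain")
  acc <- bind_rows(lapply(cats, function(cc) {
    idx <- truths == cc
    tibble(category = cc, n = sum(idx),
           accuracy = if (any(idx)) mean(predictions[idx] == cc)
                      else NA_real_)
  }))
  roc <- NULL
  if (!is.null(vote_fractions)) {
    roc <- bind_rows(lapply(cats, function(cc) {
      score <- vote_fractions[, cc]
      truth <- truths == cc
      if (!any(truth) || all(truth)) return(NULL)
      th <- sort(unique(c(-Inf, score, Inf)))
      pts <- bind_rows(lapply(th, function(t0) {
        pred <- score >= t0
        tibble(category = cc, threshold = t0,
               tpr = sum(pred & truth) / sum(truth),
               fpr = sum(pred & !truth) / sum(!truth))
      }))
      pts <- arrange(pts, .data$fpr, .data$tpr)
      auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
      pts$auc <- auc
      pts
    }))
  }
  list(accuracy = acc, roc = roc)
}
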