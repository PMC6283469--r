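#' Default per-cluster covariate profiles
#'
#' Marginal distributions of the nine clustering variables (plus pDPN duration,
#' baseline general-feeling items and maintenance dose) for each of the six
#' patient subgroups the pipeline assumes. The numbers emulate the published
#' calibration-cohort profiles: each cluster has a near-deterministic signature
#' on the dichotomous variables (e.g. an all-male pregabalin-monotherapy
#' cluster, an all-female cluster, a depression-history cluster, an
#' insulin-user cluster, a prior-gabapentin cluster and a combination-therapy
#' cluster) with overlapping age/BMI/pain/PRSI distributions.
#'
#' @param separation Optional sharpening in `[0, 1]`: 0 returns the default
#'   profiles; 1 pushes every dichotomous probability to exactly 0/1 and
#'   spreads the numeric means apart, giving fully separated clusters for
#'   recoverability experiments.
#' @return A tibble with one row per cluster; list-columns hold the level
#'   probabilities for multi-level variables (duration bins, feeling items on
#'   the 1 = always ... 6 = never scale, maintenance dose over
#'   75/150/300/600 mg/day).
#' @export
default_cluster_profiles <- function(separation = 0) {
  stopifnot(separation >= 0, separation <= 1)
  p <- tibble(
    cluster    = 1:6,
    weight     = c(431, 189, 437, 266, 127, 316) / 1766,
    p_female   = c(0.000, 0.471, 0.380, 1.000, 0.268, 0.418),
    age_mean   = c(60.2, 62.9, 62.9, 62.2, 61.3, 63.7),
    age_sd     = c(9.3, 8.6, 8.5, 8.5, 9.7, 8.3),
    bmi_mean   = c(28.1, 29.5, 29.7, 28.9, 28.5, 28.4),
    bmi_sd     = c(3.5, 4.5, 4.6, 4.6, 4.4, 3.8),
    pain_mean  = c(6.3, 7.1, 6.6, 6.4, 6.3, 6.3),
    pain_sd    = c(1.3, 1.3, 1.4, 1.3, 1.4, 1.3),
    prsi_mean  = c(5.3, 6.8, 5.9, 5.8, 5.6, 5.5),
    prsi_sd    = c(2.2, 1.9, 2.2, 1.9, 2.1, 2.0),
    p_depression  = c(0.000, 1.000, 0.021, 0.000, 0.024, 0.000),
    p_monotherapy = c(1.000, 0.349, 0.599, 1.000, 0.646, 0.000),
    p_gabapentin  = c(0.000, 0.111, 0.028, 0.000, 1.000, 0.010),
    p_insulin     = c(0.000, 0.349, 0.998, 0.015, 0.488, 0.079)
  )
  norm <- function(x) x / sum(x)
  p$duration_probs <- list(
    norm(c(28.8, 23.2, 25.5, 11.1, 3.7, 7.7)),
    norm(c(15.9, 21.7, 24.9, 15.3, 5.8, 16.4)),
    norm(c(21.3, 23.6, 24.0, 12.8, 5.5, 12.8)),
    norm(c(25.9, 21.8, 27.1, 15.4, 2.6, 7.1)),
    norm(c(24.4, 24.4, 22.8, 10.2, 7.1, 11.0)),
    norm(c(24.4, 22.2, 18.3, 18.7, 6.0, 10.4))
  )
  p$calm_probs <- list(
    norm(c(2.1, 15.3, 16.9, 32.2, 31.8, 1.6)),
    norm(c(2.1, 4.2, 9.0, 20.1, 47.6, 16.9)),
    norm(c(2.9, 11.2, 16.5, 29.9, 33.9, 5.5)),
    norm(c(0.8, 13.2, 15.8, 28.9, 38.4, 3.0)),
    norm(c(0.8, 12.6, 20.5, 29.9, 29.1, 7.1)),
    norm(c(1.3, 13.3, 13.6, 31.9, 36.7, 3.2))
  )
  p$energy_probs <- list(
    norm(c(1.2, 7.7, 13.5, 29.9, 40.6, 7.2)),
    norm(c(1.1, 1.1, 2.1, 17.5, 49.7, 28.6)),
    norm(c(0.7, 5.3, 7.1, 29.5, 43.3, 14.2)),
    norm(c(1.1, 3.4, 10.5, 31.2, 48.1, 5.6)),
    norm(c(0.0, 3.9, 13.4, 25.9, 43.3, 13.4)),
    norm(c(0.6, 4.4, 7.9, 20.9, 57.9, 8.2))
  )
  p$sad_probs <- list(
    norm(c(1.6, 15.3, 28.3, 29.3, 20.2, 5.3)),
    norm(c(6.4, 35.9, 33.3, 15.3, 8.5, 0.5)),
    norm(c(2.9, 17.6, 27.0, 29.5, 16.3, 6.6)),
    norm(c(1.9, 15.4, 26.3, 30.8, 21.8, 3.8)),
    norm(c(3.9, 15.8, 26.8, 26.8, 22.1, 4.7)),
    norm(c(1.6, 15.5, 31.0, 33.2, 15.5, 3.2))
  )
  p$dose_probs <- list(
    norm(c(3.5, 38.3, 53.8, 4.4)),
    norm(c(3.7, 31.2, 59.8, 5.3)),
    norm(c(4.8, 35.7, 54.7, 4.8)),
    norm(c(4.5, 38.7, 52.6, 4.1)),
    norm(c(2.4, 31.5, 61.4, 4.7)),
    norm(c(6.0, 34.2, 55.4, 4.4))
  )
  if (separation > 0) {
    s <- separation
    sharpen <- function(x) (1 - s) * x + s * round(x)
    for (v in c("p_female", "p_depression", "p_monotherapy",
                "p_gabapentin", "p_insulin")) {
      p[[v]] <- sharpen(p[[v]])
    }
    # spread numeric means apart and tighten spreads
    p$age_mean  <- p$age_mean + s * c(-14, 10, 4, -4, 14, 0)
    p$pain_mean <- pmin(9, p$pain_mean + s * c(-1.5, 1.8, 0.6, -0.6, 1.2, 0))
    p$prsi_mean <- pmin(9.5, p$prsi_mean + s * c(-2.5, 2.2, 0.8, -0.8, 1.6, 0))
    p$age_sd  <- p$age_sd * (1 - 0.6 * s)
    p$pain_sd <- p$pain_sd * (1 - 0.6 * s)
    p$prsi_sd <- p$prsi_sd * (1 - 0.6 * s)
  }
  p
}

#' Specify a synthetic cohort
#'
#' Bundles the sizes, mixture weights, per-cluster covariate profiles and
#' noise level from which [generate_cohort()] draws an observational-study
#' (OS) cohort and a randomized-controlled-trial (RCT) cohort.
#'
#' @param n_os,n_rct Number of OS and RCT patients.
#' @param rct_duration_split Fraction of RCT patients followed for 12/13 weeks
#'   (the remainder are 6-week trials).
#' @param cluster_weights Six nonnegative mixture weights summing to 1.
#' @param covariate_profiles Per-cluster profile tibble as produced by
#'   [default_cluster_profiles()].
#' @param noise_sd Residual SD (NRS units) of the weekly pain innovation;
#'   `0` gives the deterministic zero-noise limit.
#' @param seed Optional integer seed; when supplied, [generate_cohort()] is
#'   fully deterministic.
#' @return A `cohort_spec` object (a validated list).
#' @examples
#' spec <- cohort_spec(n_os = 100, n_rct = 50, seed = 1)
#' @export
cohort_spec <- function(n_os = 2642, n_rct = 1320,
                        rct_duration_split = 0.711,
                        cluster_weights = default_cluster_profiles()$weight,
                        covariate_profiles = default_cluster_profiles(),
                        noise_sd = 0.4, seed = NULL) {
  if (!is.numeric(n_os) || length(n_os) != 1 || n_os < 0 || n_os != round(n_os))
    abort("`n_os` must be a single nonnegative integer")
  if (!is.numeric(n_rct) || length(n_rct) != 1 || n_rct < 0 ||
      n_rct != round(n_rct))
    abort("`n_rct` must be a single nonnegative integer")
  if (!is.numeric(rct_duration_split) || rct_duration_split < 0 ||
      rct_duration_split > 1)
    abort("`rct_duration_split` must lie in [0, 1]")
  if (length(cluster_weights) != 6 || any(cluster_weights < 0))
    abort("`cluster_weights` must be 6 nonnegative fractions")
  if (abs(sum(cluster_weights) - 1) > 1e-12)
    abort("`cluster_weights` must sum to 1")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort("`noise_sd` must be a nonnegative residual SD")
  probs <- unlist(covariate_profiles[c("p_female", "p_depression",
                                       "p_monotherapy", "p_gabapentin",
                                       "p_insulin")])
  if (any(probs < 0 | probs > 1))
    abort("`covariate_profiles` probabilities must lie in [0, 1]")
  structure(
    list(n_os = as.integer(n_os), n_rct = as.integer(n_rct),
         rct_duration_split = rct_duration_split,
         cluster_weights = cluster_weights,
         covariate_profiles = covariate_profiles,
         noise_sd = noise_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_os, " OS + ", x$n_rct, " RCT patients, ",
      "6 clusters, noise_sd = ", x$noise_sd, "\n", sep = "")
  invisible(x)
}
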