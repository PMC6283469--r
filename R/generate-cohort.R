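#' Generate a synthetic OS + RCT cohort
#'
#' Draws each patient's subgroup from the mixture weights, baseline covariates
#' from that subgroup's profile, and then advances weekly pain scores with the
#' subgroup's reference lagged regression plus Gaussian innovation noise.
#' Pain-related sleep interference (PRSI) is generated as `0.6 * pain(t-1)`
#' plus an AR(1) disturbance (autocorrelation 0.5) and clipped to the 0--10
#' NRS; the disturbance is initialised so the baseline PRSI is reproduced at
#' week 0. Dose starts at 150 mg/day and switches at week 1 to a per-patient
#' maintenance dose drawn from the subgroup's dose marginals. The three
#' general-feeling items evolve as a bounded +/-1 random walk on the 1--6
#' scale. Observational-study (OS) patients are observed only at weeks
#' 0, 1, 3 and 6 (unobserved weekly values are returned as `NA` with
#' `observed = FALSE`); trial (RCT) patients are observed every week of their
#' 6-, 12- or 13-week follow-up.
#'
#' @param spec A [cohort_spec()].
#' @return A `vlab_cohort`: a list with `patients` (one row per patient) and
#'   `series` (long weekly records: `patient_id`, `week`, `pain`, `prsi`,
#'   `dose_mg`, `calm`, `energy`, `sad`, `observed`), plus the spec used.
#'   `patients$true_cluster` is the generator's ground truth and is not used
#'   by any downstream stage.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_os = 50, n_rct = 20, seed = 1))
#' coh$patients
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_os + spec$n_rct
  prof <- spec$covariate_profiles
  cl <- sample.int(6L, n, replace = TRUE, prob = spec$cluster_weights)
  src <- rep(c("OS", "RCT"), c(spec$n_os, spec$n_rct))
  pr <- prof[cl, ]

  rtrunc <- function(m, s, lo, hi) {
    s <- pmax(s, 1e-9)
    a <- pnorm(lo, m, s); b <- pnorm(hi, m, s)
    qnorm(a + runif(length(m)) * (b - a), m, s)
  }
  draw_levels <- function(levels, problist) {
    out <- vector(mode = typeof(levels), length = n)
    for (c6 in 1:6) {
      idx <- which(cl == c6)
      if (length(idx))
        out[idx] <- sample(levels, length(idx), replace = TRUE,
                           prob = problist[[c6]])
    }
    out
  }

  age   <- as.integer(round(rtrunc(pr$age_mean, pr$age_sd, 18, 90)))
  bmi   <- rtrunc(pr$bmi_mean, pr$bmi_sd, 16, 55)
  pain0 <- rtrunc(pr$pain_mean, pr$pain_sd, 4, 10)
  prsi0 <- rtrunc(pr$prsi_mean, pr$prsi_sd, 0, 10)
  female <- runif(n) < pr$p_female
  insulin <- runif(n) < pr$p_insulin
  depression <- runif(n) < pr$p_depression
  gabapentin <- runif(n) < pr$p_gabapentin
  monotherapy <- runif(n) < pr$p_monotherapy
  duration_group <- draw_levels(duration_group_levels(), prof$duration_probs)
  calm0   <- draw_levels(1:6, prof$calm_probs)
  energy0 <- draw_levels(1:6, prof$energy_probs)
  sad0    <- draw_levels(1:6, prof$sad_probs)
  dose_maint <- draw_levels(dose_levels(), prof$dose_probs)

  long_rct <- src == "RCT" & runif(n) < spec$rct_duration_split
  duration <- ifelse(src == "OS", 6L,
                     ifelse(long_rct, sample(c(12L, 13L), n, replace = TRUE),
                            6L))

  patients <- tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    source = src,
    true_cluster = cl,
    gender = ifelse(female, "F", "M"),
    age_years = age,
    age_group = age_group_of(age),
    bmi_kg_m2 = bmi,
    bmi_group = bmi_group_of(bmi),
    insulin = insulin,
    depression_history = depression,
    prior_gabapentin = gabapentin,
    pregabalin_monotherapy = monotherapy,
    pdpn_duration_group = duration_group,
    baseline_pain = pain0,
    baseline_prsi = prsi0,
    calm_baseline = calm0,
    energy_baseline = energy0,
    sad_baseline = sad0,
    maintenance_dose = dose_maint,
    duration_weeks = as.integer(duration)
  )

  # weekly trajectories, vectorised across patients
  terms <- c("pain_lag1", "prsi_lag0", "prsi_lag3", "dose_lag3",
             "age_75plus", "calm_baseline", "energy_baseline")
  B <- matrix(0, 6, length(terms), dimnames = list(NULL, terms))
  ref <- reference_cluster_models()
  for (i in seq_len(nrow(ref))) B[ref$cluster[i], ref$term[i]] <- ref$estimate[i]
  Bp <- B[cl, , drop = FALSE]

  max_t <- max(duration)
  clip01 <- function(x) pmin(10, pmax(0, x))
  P <- Sm <- matrix(NA_real_, n, max_t + 1)
  D <- matrix(NA_real_, n, max_t + 1)
  C <- E <- Sd <- matrix(NA_integer_, n, max_t + 1)
  P[, 1] <- pain0; Sm[, 1] <- prsi0; D[, 1] <- 150
  C[, 1] <- calm0; E[, 1] <- energy0; Sd[, 1] <- sad0
  ar <- prsi0 - 0.6 * pain0
  x5 <- as.numeric(patients$age_group == "75+")
  step_walk <- function(v) {
    pmin(6L, pmax(1L, v + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                 prob = c(0.15, 0.7, 0.15))))
  }
  for (t in seq_len(max_t)) {
    D[, t + 1] <- dose_maint
    ar <- 0.5 * ar + rnorm(n, 0, spec$noise_sd)
    Sm[, t + 1] <- clip01(0.6 * P[, t] + ar)
    l3 <- max(t - 3, 0) + 1
    X <- cbind(P[, t], Sm[, t + 1], Sm[, l3], D[, l3], x5, calm0, energy0)
    P[, t + 1] <- clip01(rowSums(X * Bp) + rnorm(n, 0, spec$noise_sd))
    C[, t + 1] <- step_walk(C[, t])
    E[, t + 1] <- step_walk(E[, t])
    Sd[, t + 1] <- step_walk(Sd[, t])
  }

  weeks_per <- duration + 1L
  idx <- rep(seq_len(n), weeks_per)
  wk <- unlist(lapply(duration, function(d) 0:d), use.names = FALSE)
  flat <- function(M) M[cbind(idx, wk + 1L)]
  series <- tibble(
    patient_id = patients$patient_id[idx],
    week = wk,
    pain = flat(P), prsi = flat(Sm), dose_mg = flat(D),
    calm = flat(C), energy = flat(E), sad = flat(Sd),
    observed = ifelse(src[idx] == "OS", wk %in% c(0L, 1L, 3L, 6L), TRUE)
  )
  # OS records are down-sampled to the week {0,1,3,6} visit schedule
  hide <- !series$observed
  series$pain[hide] <- NA_real_
  series$prsi[hide] <- NA_real_
  series$calm[hide] <- NA_integer_
  series$energy[hide] <- NA_integer_
  series$sad[hide] <- NA_integer_

  structure(list(patients = patients, series = series, spec = spec),
            class = "vlab_cohort")
}

#' @export
print.vlab_cohort <- function(x, ...) {
  cat("<vlab_cohort> ", sum(x$patients$source == "OS"), " OS + ",
      sum(x$patients$source == "RCT"), " RCT patients; ",
      nrow(x$series), " weekly records\n", sep = "")
  invisible(x)
}

#' Inject OS selection bias into a synthetic cohort
#'
#' Observational cohorts are not randomized, so their covariate marginals
#' typically differ from trial populations. This helper creates that
#' imbalance in a synthetic cohort by perturbing the OS patients' covariates:
#' binary exposures (insulin, depression history, prior gabapentin) are
#' switched on with probability `strength / 2`, gender is nudged toward
#' female with probability `strength / 4`, ages are shifted upward and BMI is
#' shifted by `1.5 * strength` kg/m2 (derived group labels are recomputed).
#' Baseline pain/PRSI and the weekly series are untouched so trajectories
#' remain consistent. `strength = 0` returns the cohort unchanged.
#'
#' @param cohort A `vlab_cohort`.
#' @param strength Nonnegative bias strength; 0 is a no-op.
#' @return The cohort with perturbed OS covariates.
#' @export
inject_selection_bias <- function(cohort, strength) {
  stopifnot(inherits(cohort, "vlab_cohort"))
  if (!is.numeric(strength) || length(strength) != 1 || strength < 0)
    abort("`strength` must be a single nonnegative number")
  if (strength == 0) return(cohort)
  p <- cohort$patients
  os <- p$source == "OS"
  n_os <- sum(os)
  flip_on <- function(v) ifelse(runif(n_os) < strength / 2, TRUE, v)
  p$insulin[os] <- flip_on(p$insulin[os])
  p$depression_history[os] <- flip_on(p$depression_history[os])
  p$prior_gabapentin[os] <- flip_on(p$prior_gabapentin[os])
  p$gender[os] <- ifelse(runif(n_os) < strength / 4, "F", p$gender[os])
  p$age_years[os] <- pmin(90L, p$age_years[os] +
                            as.integer(round(strength * runif(n_os, 0, 8))))
  p$bmi_kg_m2[os] <- pmin(55, p$bmi_kg_m2[os] + 1.5 * strength)
  p$age_group[os] <- age_group_of(p$age_years[os])
  p$bmi_group[os] <- bmi_group_of(p$bmi_kg_m2[os])
  cohort$patients <- p
  cohort
}
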