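# Fixtures are generated in code; nothing is read from disk.

# A small mixed cohort. `separation = 1` gives fully separated cluster
# profiles (dichotomous signatures pushed to 0/1, numeric means spread), the
# configuration under which ground-truth recoverability is asserted.
small_cohort <- function(n_os = 200, n_rct = 100, noise_sd = 0.4, seed = 42,
                         separation = 0, rct_duration_split = 0.711) {
  generate_cohort(cohort_spec(
    n_os = n_os, n_rct = n_rct, rct_duration_split = rct_duration_split,
    covariate_profiles = default_cluster_profiles(separation),
    noise_sd = noise_sd, seed = seed
  ))
}

# Minimal patient records carrying the nine clustering variables (plus the
# extra columns other stages expect), with overridable fields.
toy_patients <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    source = "OS",
    gender = "M",
    age_years = 60L,
    bmi_kg_m2 = 27,
    insulin = FALSE,
    depression_history = FALSE,
    prior_gabapentin = FALSE,
    pregabalin_monotherapy = TRUE,
    baseline_pain = 6,
    baseline_prsi = 5,
    calm_baseline = 3L,
    energy_baseline = 4L,
    sad_baseline = 3L,
    duration_weeks = 6L
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$age_group <- age_group_of(base$age_years)
  base$bmi_group <- bmi_group_of(base$bmi_kg_m2)
  base
}

# Constant weekly series for a set of patients (used to build degenerate
# neighbourhoods whose empirical distributions collapse to a point).
toy_series <- function(patient_ids, pain, prsi = 5, dose = 300,
                       weeks = 0:6) {
  stopifnot(length(pain) == length(weeks))
  tibble::tibble(
    patient_id = rep(patient_ids, each = length(weeks)),
    week = rep(weeks, length(patient_ids)),
    pain = rep(pain, length(patient_ids)),
    prsi = prsi, dose_mg = dose, calm = 3L, energy = 4L, sad = 3L,
    observed = TRUE
  )
}

# Wrap a named coefficient vector as a fitted cluster model.
as_fit <- function(coefficients, cluster_id = 1L) {
  structure(
    list(cluster_id = cluster_id, method = "reference",
         coefficients = coefficients, lambda = NA_real_, alpha = NA_real_,
         adjusted_r2 = NA_real_, r2 = NA_real_, rmse = NA_real_,
         lr_p = NA_real_, n = NA_integer_, selection_trace = NULL),
    class = "vlab_fit"
  )
}

reference_fits <- function() {
  fits <- lapply(1:6, function(k) as_fit(reference_coefficients(k), k))
  names(fits) <- as.character(1:6)
  structure(fits, class = "vlab_fits")
}

# Independent polynomial oracle: exact interpolating polynomial through
# (x, y) points via Vandermonde solve.
poly_oracle <- function(x, y, x0) {
  V <- outer(x, seq_along(x) - 1, "^")
  as.numeric(outer(x0, seq_along(x) - 1, "^") %*% solve(V, y))
}
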