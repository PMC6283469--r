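test_that("design rows exist only where the required lags are available", {
  p <- toy_patients(1)
  s <- toy_series(p$patient_id, pain = c(6, 5.5, 5, 4.5, 4, 3.5, 3),
                  dose = c(150, 150, 300, 300, 300, 300, 300))
  des <- suppressMessages(build_design(s, p, c("pain_lag1", "prsi_lag0",
                                               "prsi_lag3", "dose_lag3")))
  expect_equal(des$week, 3:6)
  # dose at week 5 with a 3-week lag looks up the week-2 dose
  expect_equal(des$dose_lag3[des$week == 5], 300)
  expect_equal(des$dose_lag3[des$week == 3], 150)
  expect_equal(des$pain_lag1, c(5, 4.5, 4, 3.5))
})

test_that("design values equal a hand-built table on a fixture series", {
  p <- toy_patients(1, calm_baseline = 2L, energy_baseline = 5L)
  pain <- c(7, 6, 5.2, 4.6, 4.1, 3.7, 3.4)
  prsi <- c(6, 5, 4.5, 4, 3.6, 3.3, 3.1)
  dose <- c(150, 300, 300, 600, 600, 600, 600)
  s <- tibble::tibble(patient_id = p$patient_id, week = 0:6, pain = pain,
                      prsi = prsi, dose_mg = dose, calm = 2L, energy = 5L,
                      sad = 3L, observed = TRUE)
  terms <- c("pain_lag1", "prsi_lag0", "prsi_lag3", "dose_lag3",
             "age_75plus", "calm_baseline", "energy_baseline")
  des <- suppressMessages(build_design(s, p, terms))
  w <- 4  # hand-check one row completely
  row <- des[des$week == w, ]
  expect_equal(row$y, pain[w + 1])
  expect_equal(row$pain_lag1, pain[w])
  expect_equal(row$prsi_lag0, prsi[w + 1])
  expect_equal(row$prsi_lag3, prsi[w - 2])
  expect_equal(row$dose_lag3, dose[w - 2])
  expect_equal(row$age_75plus, 0)
  expect_equal(row$calm_baseline, 2)
  expect_equal(row$energy_baseline, 5)
  expect_error(suppressMessages(build_design(s, p, "nonsense_lag9")),
               "unknown predictor")
})

test_that("cross-correlation screening ranks signal above noise", {
  set.seed(7)
  n <- 1000
  phi <- 0.7
  x <- as.numeric(stats::arima.sim(list(ar = phi), n + 1))
  des <- tibble::tibble(patient_id = "a", week = seq_len(n), y = x[-1],
                        self = x[-1], lag1 = x[-(n + 1)],
                        noise = stats::rnorm(n), flat = 1)
  expect_warning(scr <- cross_correlation_screen(des), "constant")
  expect_equal(scr$r[scr$term == "self"], 1, tolerance = 1e-12)
  # AR(1): lag-1 autocorrelation approaches the AR coefficient
  expect_equal(scr$r[scr$term == "lag1"], phi, tolerance = 0.08)
  expect_lt(abs(scr$r[scr$term == "noise"]), 0.1)
  expect_equal(scr$r[scr$term == "flat"], 0)
  expect_equal(scr$term[1], "self")
  expect_error(cross_correlation_screen(des[1:5, ]), "10")
})

test_that("stepwise selection recovers a single-predictor model", {
  set.seed(11)
  n <- 300
  des <- tibble::tibble(
    patient_id = "a", week = seq_len(n),
    x1 = stats::runif(n, 2, 9), z1 = stats::rnorm(n), z2 = stats::rnorm(n)
  )
  des$y <- 0.7 * des$x1 + stats::rnorm(n, 0, 0.01)
  fit <- fit_stepwise_ml(des, c("x1", "z1", "z2"))
  expect_setequal(names(fit$coefficients), "x1")
  expect_equal(unname(fit$coefficients["x1"]), 0.7, tolerance = 0.05)
  expect_true(all(c("add") %in% fit$selection_trace$action))
  # pure-noise candidates leave the model empty
  des$y <- stats::rnorm(n)
  fit0 <- fit_stepwise_ml(des, c("z1", "z2"))
  expect_length(fit0$coefficients, 0)
})

test_that("stepwise selection on equation-generated data stays within the true set", {
  set.seed(13)
  n <- 400
  des <- tibble::tibble(
    patient_id = "a", week = seq_len(n),
    pain_lag1 = stats::runif(n, 1, 9),
    prsi_lag0 = stats::runif(n, 0, 10),
    prsi_lag3 = stats::runif(n, 0, 10),
    dose_lag3 = sample(c(75, 150, 300, 600), n, replace = TRUE),
    age_75plus = stats::rbinom(n, 1, 0.07),
    calm_baseline = sample(1:6, n, replace = TRUE),
    energy_baseline = sample(1:6, n, replace = TRUE)
  )
  truth <- reference_coefficients(1)
  des$y <- 0.6229 * des$pain_lag1 + 0.2461 * des$prsi_lag0 +
    0.0002 * des$dose_lag3 + 0.0354 * des$calm_baseline +
    stats::rnorm(n, 0, 0.4)
  fit <- fit_stepwise_ml(des, setdiff(names(des),
                                      c("patient_id", "week", "y")))
  expect_true(all(names(fit$coefficients) %in% names(truth)))
  expect_true("pain_lag1" %in% names(fit$coefficients))
  expect_equal(unname(fit$coefficients["pain_lag1"]), 0.6229,
               tolerance = 0.05)
})

test_that("penalized fits honour the shrinkage limits", {
  set.seed(17)
  n <- 200
  des <- tibble::tibble(
    patient_id = "a", week = seq_len(n),
    x1 = stats::runif(n, 0, 10), x2 = stats::runif(n, 0, 10),
    x3 = stats::rnorm(n)
  )
  des$y <- 0.6 * des$x1 + 0.25 * des$x2 + stats::rnorm(n, 0, 0.3)
  cands <- c("x1", "x2", "x3")
  # total shrinkage
  f_inf <- fit_penalized(des, cands, method = "lasso", lambda = 1e6)
  expect_length(f_inf$coefficients, 0)
  # unpenalized limit equals ordinary least squares
  f0 <- fit_penalized(des, cands, method = "lasso", lambda = 0)
  ols <- stats::lm.fit(as.matrix(des[cands]), des$y)$coefficients
  expect_equal(f0$coefficients, ols, tolerance = 1e-6)
  expect_error(fit_penalized(des, cands, lambda = c(1, 2)), "degenerate")
  # sparsity is nonincreasing along increasing penalty
  nz <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(l) {
    length(fit_penalized(des, cands, method = "lasso",
                         lambda = l)$coefficients)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("the three penalized methods agree on a clean fixture", {
  set.seed(19)
  n <- 400
  des <- tibble::tibble(
    patient_id = "a", week = seq_len(n),
    x1 = stats::runif(n, 0, 10), x2 = stats::runif(n, 0, 10),
    x3 = stats::rnorm(n), x4 = stats::rnorm(n)
  )
  des$y <- 0.62 * des$x1 + 0.24 * des$x2 + stats::rnorm(n, 0, 0.3)
  cands <- c("x1", "x2", "x3", "x4")
  fits <- lapply(c("lasso", "adaptive_lasso", "elastic_net"), function(m) {
    set.seed(99)
    fit_penalized(des, cands, method = m)
  })
  full <- function(f) {
    out <- setNames(numeric(4), cands)
    out[names(f$coefficients)] <- f$coefficients
    out
  }
  betas <- lapply(fits, full)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(betas[[i]], betas[[j]], tolerance = 0.1)
  for (f in fits) expect_gt(f$adjusted_r2, 0.95)
})

test_that("predict_pain is the exact no-intercept inner product", {
  co1 <- reference_coefficients(1)
  expect_equal(predict_pain(co1, c(pain_lag1 = 0, prsi_lag0 = 0,
                                   dose_lag3 = 0, calm_baseline = 0)), 0)
  got <- predict_pain(co1, c(pain_lag1 = 6, prsi_lag0 = 5,
                             dose_lag3 = 300, calm_baseline = 3))
  expect_equal(got, 0.6229 * 6 + 0.2461 * 5 + 0.0002 * 300 + 0.0354 * 3,
               tolerance = 1e-12)
  # linearity (no intercept): f(a v) = a f(v)
  v <- c(pain_lag1 = 4, prsi_lag0 = 3, dose_lag3 = 150, calm_baseline = 2)
  expect_equal(predict_pain(co1, 3 * v), 3 * predict_pain(co1, v),
               tolerance = 1e-12)
  # cluster 2: raising PRSI(t-3) strictly lowers the prediction
  co2 <- reference_coefficients(2)
  base <- c(pain_lag1 = 6, prsi_lag0 = 5, prsi_lag3 = 4, dose_lag3 = 300,
            age_75plus = 0, calm_baseline = 3)
  up <- base; up["prsi_lag3"] <- 6
  expect_lt(predict_pain(co2, up), predict_pain(co2, base))
  expect_error(predict_pain(co1, c(pain_lag1 = 6)), "prsi_lag0")
})

test_that("holdout validation separates faithful and shifted predictions", {
  # noise_sd 0.2 against a within-cluster weekly score variance of ~0.5
  # keeps the observed-vs-predicted scatter R^2 above 0.9 in every cluster
  coh <- small_cohort(n_os = 0, n_rct = 120, noise_sd = 0.2, seed = 37,
                      rct_duration_split = 0)
  labels <- tibble::tibble(patient_id = coh$patients$patient_id,
                           cluster = coh$patients$true_cluster)
  fits <- reference_fits()
  rep <- suppressWarnings(suppressMessages(
    validate_holdout(fits, coh$patients, coh$series, labels,
                     predictors = core_predictors())))
  expect_true(all(rep$r2 >= 0.9))
  expect_true(all(rep$t_p > 0.05))
  # a constant +5 shift is rejected by the two-sample t-test
  shifted <- reference_fits()
  s <- coh$series
  s$pain <- pmin(10, s$pain + 5)
  des_p <- coh$patients
  r2 <- suppressWarnings(suppressMessages(
    validate_holdout(shifted, des_p, s, labels,
                     predictors = core_predictors())))
  expect_true(any(r2$t_p < 0.01))
})

test_that("model JSON serialization round-trips", {
  fits <- reference_fits()
  path <- withr::local_tempfile(fileext = ".json")
  write_models(fits, path)
  back <- read_models(path)
  expect_equal(names(back), names(fits))
  for (k in names(fits))
    expect_equal(back[[k]]$coefficients, fits[[k]]$coefficients)
})
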