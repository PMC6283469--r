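#' Candidate predictor dictionary for the lagged pain regressions
#'
#' Weekly pain at week `t` is modelled from lagged values of pain, PRSI and
#' dose, the baseline general-feeling items, and fixed covariates. Terms are
#' named `<var>_lag<k>` for time-varying variables (`k` weeks before the
#' predicted week; lag 0 is the concurrent value) and by covariate name
#' otherwise. The canonical published predictor set is
#' [core_predictors()]: pain at lag 1, concurrent PRSI, PRSI and dose at lag
#' 3, the 75+ age-cohort dummy and the baseline calm/energy feeling items.
#'
#' @param pain_lags,prsi_lags,dose_lags Integer lag vectors.
#' @param feelings Include the three baseline feeling items.
#' @param fixed Include the fixed covariate dummies.
#' @return Tibble with columns `term`, `var`, `lag`, `kind`.
#' @export
predictor_dictionary <- function(pain_lags = 1:3, prsi_lags = 0:3,
                                 dose_lags = 0:3, feelings = TRUE,
                                 fixed = TRUE) {
  if (any(c(pain_lags, prsi_lags, dose_lags) < 0))
    abort("lag indices must be nonnegative")
  if (any(pain_lags == 0))
    abort("pain at lag 0 is the response and cannot be a predictor")
  lagged <- bind_rows(
    tibble(var = "pain", lag = as.integer(pain_lags)),
    tibble(var = "prsi", lag = as.integer(prsi_lags)),
    tibble(var = "dose", lag = as.integer(dose_lags))
  ) %>% mutate(term = paste0(.data$var, "_lag", .data$lag), kind = "lagged")
  extra <- NULL
  if (feelings) {
    fe <- c("calm_baseline", "energy_baseline", "sad_baseline")
    extra <- tibble(term = fe, var = fe, lag = NA_integer_, kind = "baseline")
  }
  fixed_terms <- NULL
  if (fixed) {
    fx <- c("age_75plus", "female", "depression", "gabapentin",
            "monotherapy", "insulin_use")
    fixed_terms <- tibble(term = fx, var = fx, lag = NA_integer_,
                          kind = "fixed")
  }
  bind_rows(lagged, extra, fixed_terms) %>%
    select("term", "var", "lag", "kind")
}

#' @rdname predictor_dictionary
#' @export
core_predictors <- function() {
  c("pain_lag1", "prsi_lag0", "prsi_lag3", "dose_lag3",
    "age_75plus", "calm_baseline", "energy_baseline")
}

#' Build the regression design table
#'
#' One row per (patient, week) with the response `y` (pain at the week) and
#' every requested predictor evaluated; weeks lacking a required lag, or with
#' any missing value, are dropped (a count is reported).
#'
#' @param series Long weekly series (imputed so weeks are consecutive).
#' @param patients Patient tibble supplying the fixed covariates.
#' @param predictors Character vector of term names (see
#'   [predictor_dictionary()]).
#' @return Tibble: `patient_id`, `week`, `y`, then one column per predictor.
#' @export
build_design <- function(series, patients, predictors = core_predictors()) {
  fixed_map <- list(
    age_75plus = function(p) as.numeric(p$age_group == "75+"),
    female = function(p) as.numeric(p$gender == "F"),
    depression = function(p) as.numeric(p$depression_history),
    gabapentin = function(p) as.numeric(p$prior_gabapentin),
    monotherapy = function(p) as.numeric(p$pregabalin_monotherapy),
    insulin_use = function(p) as.numeric(p$insulin),
    calm_baseline = function(p) as.numeric(p$calm_baseline),
    energy_baseline = function(p) as.numeric(p$energy_baseline),
    sad_baseline = function(p) as.numeric(p$sad_baseline)
  )
  varcol <- c(pain = "pain", prsi = "prsi", dose = "dose_mg")
  df <- series %>% arrange(.data$patient_id, .data$week) %>%
    group_by(.data$patient_id)
  out <- df %>% mutate(y = .data$pain) %>% ungroup() %>%
    select("patient_id", "week", "y")
  for (term in predictors) {
    m <- regmatches(term, regexec("^(pain|prsi|dose)_lag([0-9]+)$", term))[[1]]
    if (length(m)) {
      k <- as.integer(m[3])
      col <- varcol[[m[2]]]
      v <- df %>%
        mutate(v = dplyr::lag(.data[[col]], k)) %>% ungroup() %>% pull("v")
      out[[term]] <- v
    } else if (!is.null(fixed_map[[term]])) {
      vals <- setNames(fixed_map[[term]](patients), patients$patient_id)
      out[[term]] <- as.numeric(vals[out$patient_id])
    } else {
      abort(paste0("unknown predictor term `", term, "`"))
    }
  }
  keep <- out$week >= 1 & complete.cases(out)
  dropped <- sum(!keep) - sum(out$week == 0)
  if (dropped > 0)
    rlang::inform(paste0("build_design: dropped ", dropped,
                         " week rows lacking a required lag or value"))
  out[keep, ]
}

#' Rank candidate predictors by cross-correlation with the response
#'
#' Pearson correlation of `y` with each candidate column of the design,
#' ranked by absolute value. Used to screen which lags carry signal before
#' model selection. Constant candidates are reported with `r = 0` and a
#' warning.
#'
#' @param design Design tibble from [build_design()] (>= 10 rows).
#' @param candidates Candidate columns (default: all predictor columns).
#' @return Tibble `term`, `r`, `abs_r`, sorted by `abs_r` descending.
#' @export
cross_correlation_screen <- function(design, candidates = NULL) {
  if (nrow(design) < 10) abort("need at least 10 design rows to screen")
  if (is.null(candidates))
    candidates <- setdiff(names(design), c("patient_id", "week", "y"))
  r <- vapply(candidates, function(v) {
    x <- design[[v]]
    if (sd(x) == 0) {
      warn(paste0("candidate `", v, "` is constant; correlation reported as 0"))
      return(0)
    }
    cor(design$y, x)
  }, numeric(1))
  tibble(term = candidates, r = unname(r), abs_r = abs(unname(r))) %>%
    arrange(dplyr::desc(.data$abs_r))
}

fit_metrics <- function(y, yhat, p) {
  n <- length(y)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  # Gaussian likelihood-ratio test against the empty (zero) model
  rss0 <- sum(y^2)
  lr <- n * log(rss0 / max(rss, 1e-300))
  list(r2 = r2, adjusted_r2 = adj, rmse = sqrt(rss / n),
       lr_p = if (p > 0) pchisq(lr, df = p, lower.tail = FALSE) else 1)
}

new_vlab_fit <- function(coefficients, method, n, metrics,
                         cluster_id = NA_integer_, lambda = NA_real_,
                         alpha = NA_real_, trace = NULL) {
  structure(
    list(cluster_id = cluster_id, method = method,
         coefficients = coefficients, lambda = lambda, alpha = alpha,
         adjusted_r2 = metrics$adjusted_r2, r2 = metrics$r2,
         rmse = metrics$rmse, lr_p = metrics$lr_p, n = n,
         selection_trace = trace),
    class = "vlab_fit"
  )
}

#' Stepwise maximum-likelihood selection of a lagged pain model
#'
#' Gaussian linear model without intercept (pain predictions from all-zero
#' inputs are zero by construction). Forward steps add the candidate with the
#' smallest likelihood-ratio p-value while it is below `alpha_in`; backward
#' steps drop terms whose removal p-value exceeds `alpha_out`; iterate to
#' stability. Candidates that are collinear with the current model (NA least
#' squares coefficient) are skipped with a warning.
#'
#' @param design Design tibble from [build_design()].
#' @param candidates Candidate term names (default: all predictor columns).
#' @param alpha_in,alpha_out Entry / removal p-value thresholds.
#' @param cluster_id Optional id recorded in the fit.
#' @return A `vlab_fit` with coefficients, fit metrics and the add/drop trace.
#' @export
fit_stepwise_ml <- function(design, candidates = NULL, alpha_in = 0.05,
                            alpha_out = 0.10, cluster_id = NA_integer_) {
  if (is.null(candidates))
    candidates <- setdiff(names(design), c("patient_id", "week", "y"))
  if (nrow(design) < length(candidates) + 5)
    abort("need at least `length(candidates) + 5` design rows")
  y <- design$y
  n <- length(y)
  rss_of <- function(terms) {
    if (!length(terms)) return(list(rss = sum(y^2), coef = numeric(0)))
    X <- as.matrix(design[terms])
    fit <- lm.fit(X, y)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  lr_p <- function(rss_small, rss_big, df) {
    stat <- n * log(rss_small / max(rss_big, 1e-300))
    pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  current <- character(0)
  cur <- rss_of(current)
  trace <- list()
  repeat {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      ps <- vapply(pool, function(tm) {
        cand <- rss_of(c(current, tm))
        if (anyNA(cand$coef)) {
          warn(paste0("candidate `", tm, "` is collinear with the model; skipped"))
          return(NA_real_)
        }
        lr_p(cur$rss, cand$rss, 1)
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < alpha_in) {
        best <- pool[which.min(ps)]
        current <- c(current, best)
        cur <- rss_of(current)
        trace[[length(trace) + 1]] <-
          tibble(action = "add", term = best, p = min(ps, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward
    if (length(current)) {
      ps <- vapply(current, function(tm) {
        lr_p(rss_of(setdiff(current, tm))$rss, cur$rss, 1)
      }, numeric(1))
      if (max(ps) > alpha_out) {
        worst <- current[which.max(ps)]
        current <- setdiff(current, worst)
        cur <- rss_of(current)
        trace[[length(trace) + 1]] <-
          tibble(action = "drop", term = worst, p = max(ps))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  coefs <- if (length(current)) setNames(as.numeric(cur$coef), current)
           else setNames(numeric(0), character(0))
  yhat <- if (length(current)) as.matrix(design[current]) %*% coefs else rep(0, n)
  new_vlab_fit(coefs, "stepwise_ml", n, fit_metrics(y, as.numeric(yhat),
                                                    length(current)),
               cluster_id = cluster_id,
               trace = if (length(trace)) bind_rows(trace) else
                 tibble(action = character(0), term = character(0),
                        p = numeric(0)))
}

#' Penalized re-estimation of a lagged pain model
#'
#' LASSO (L1), adaptive LASSO (weighted L1 with weights `1/|b_OLS|`) or
#' elastic net (mixed L1+L2, mixing `alpha`) fits without intercept, solved
#' by coordinate descent via \pkg{glmnet}. The penalty strength is tuned by
#' K-fold cross-validation at the CV-minimum unless `lambda` is supplied;
#' `lambda = 0` returns the exact unpenalized least-squares solution.
#'
#' @param design Design tibble from [build_design()].
#' @param candidates Candidate term names.
#' @param method `"lasso"`, `"adaptive_lasso"` or `"elastic_net"`.
#' @param nfolds Cross-validation folds.
#' @param lambda Optional fixed penalty (scalar) instead of CV tuning.
#' @param alpha Elastic-net mixing parameter (only for `"elastic_net"`).
#' @param cluster_id Optional id recorded in the fit.
#' @return A `vlab_fit`; coefficients exactly zeroed by the penalty are
#'   dropped from the map.
#' @export
fit_penalized <- function(design, candidates = NULL,
                          method = c("lasso", "adaptive_lasso", "elastic_net"),
                          nfolds = 10, lambda = NULL, alpha = 0.5,
                          cluster_id = NA_integer_) {
  method <- match.arg(method)
  if (is.null(candidates))
    candidates <- setdiff(names(design), c("patient_id", "week", "y"))
  if (nrow(design) < length(candidates) + 5)
    abort("need at least `length(candidates) + 5` design rows")
  y <- design$y
  X <- as.matrix(design[candidates])
  n <- length(y)
  if (!is.null(lambda)) {
    if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
      abort("`lambda` grid is degenerate; supply a single nonnegative value")
    if (lambda == 0) {  # unpenalized limit: exact least squares
      fit <- lm.fit(X, y)
      coefs <- setNames(as.numeric(fit$coefficients), candidates)
      yhat <- as.numeric(X %*% coefs)
      return(new_vlab_fit(coefs, method, n, fit_metrics(y, yhat, ncol(X)),
                          cluster_id = cluster_id, lambda = 0,
                          alpha = if (method == "elastic_net") alpha else 1))
    }
  }
  mix <- switch(method, lasso = 1, adaptive_lasso = 1, elastic_net = alpha)
  pf <- rep(1, ncol(X))
  if (method == "adaptive_lasso") {
    b0 <- lm.fit(X, y)$coefficients
    b0[is.na(b0)] <- 0
    pf <- 1 / pmax(abs(b0), 1e-6)
  }
  if (!is.null(lambda)) {
    gfit <- glmnet::glmnet(X, y, alpha = mix, intercept = FALSE,
                           penalty.factor = pf,
                           lambda = sort(lambda * c(8, 4, 2, 1),
                                         decreasing = TRUE))
    beta <- as.numeric(coef(gfit, s = lambda, exact = FALSE))[-1]
    lam <- lambda
  } else {
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(X, y, alpha = mix, intercept = FALSE,
                            penalty.factor = pf, foldid = foldid)
    beta <- as.numeric(coef(cv, s = "lambda.min"))[-1]
    lam <- cv$lambda.min
  }
  names(beta) <- candidates
  coefs <- beta[beta != 0]
  yhat <- as.numeric(X %*% beta)
  new_vlab_fit(coefs, method, n, fit_metrics(y, yhat, length(coefs)),
               cluster_id = cluster_id, lambda = lam,
               alpha = if (method == "elastic_net") alpha else 1)
}

#' Predict a weekly pain score from a fitted cluster model
#'
#' The prediction is the inner product of the model coefficients with the
#' supplied predictor values -- there is no intercept, so an all-zero input
#' predicts 0. Values are not clipped here; the simulation layer clips to
#' the 0--10 NRS after each weekly update.
#'
#' @param model A `vlab_fit` (or a named coefficient vector).
#' @param values Named list/vector, or a tibble with one column per
#'   predictor (vectorised over rows).
#' @return Numeric prediction(s).
#' @examples
#' predict_pain(reference_coefficients(1),
#'              c(pain_lag1 = 6, prsi_lag0 = 5, dose_lag3 = 300,
#'                calm_baseline = 3))
#' @export
predict_pain <- function(model, values) {
  coefs <- if (inherits(model, "vlab_fit")) model$coefficients else model
  if (is.data.frame(values)) {
    missing <- setdiff(names(coefs), names(values))
    if (length(missing))
      abort(paste0("missing predictor value(s): ",
                   paste(missing, collapse = ", ")))
    if (!length(coefs)) return(rep(0, nrow(values)))
    return(as.numeric(as.matrix(values[names(coefs)]) %*% coefs))
  }
  values <- unlist(values)
  missing <- setdiff(names(coefs), names(values))
  if (length(missing))
    abort(paste0("missing predictor value(s): ",
                 paste(missing, collapse = ", ")))
  if (!length(coefs)) return(0)
  sum(coefs * values[names(coefs)])
}

#' @export
print.vlab_fit <- function(x, ...) {
  cat("<vlab_fit> cluster ", x$cluster_id, " (", x$method, "): ",
      length(x$coefficients), " terms, adj R² ",
      sprintf("%.3f", x$adjusted_r2), ", RMSE ", sprintf("%.3f", x$rmse),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_stepwise_ml Coefficients as a tibble.
#' @param x A `vlab_fit`.
#' @param ... Unused.
#' @export
#' @method tidy vlab_fit
tidy.vlab_fit <- function(x, ...) {
  tibble(cluster = x$cluster_id, term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @describeIn fit_stepwise_ml One-row fit summary.
#' @export
#' @method glance vlab_fit
glance.vlab_fit <- function(x, ...) {
  tibble(cluster = x$cluster_id, method = x$method,
         n_terms = length(x$coefficients), lambda = x$lambda,
         alpha = x$alpha, r2 = x$r2, adjusted_r2 = x$adjusted_r2,
         rmse = x$rmse, lr_p = x$lr_p, n = x$n)
}

#' Fit one lagged pain model per cluster
#'
#' Convenience wrapper: builds the per-cluster design over the calibration
#' patients and fits either the stepwise maximum-likelihood model or a
#' penalized model for every cluster.
#'
#' @param patients Calibration patients (must include the model covariates).
#' @param series Imputed weekly series for those patients.
#' @param labels Tibble `patient_id`, `cluster` (patients may appear in
#'   several clusters, as after multi-cluster matching).
#' @param predictors Candidate terms.
#' @param method `"stepwise_ml"`, `"lasso"`, `"adaptive_lasso"` or
#'   `"elastic_net"`.
#' @param ... Passed to the underlying fitter.
#' @return A `vlab_fits`: list of `vlab_fit` keyed by cluster id.
#' @export
fit_cluster_models <- function(patients, series, labels,
                               predictors = core_predictors(),
                               method = "lasso", ...) {
  ks <- sort(unique(labels$cluster))
  fits <- lapply(ks, function(k) {
    ids <- labels$patient_id[labels$cluster == k]
    p <- patients[patients$patient_id %in% ids, ]
    s <- series[series$patient_id %in% ids, ]
    cands <- predictors
    des <- build_design(s, p, cands)
    if (nrow(des) < length(cands) + 5) {
      # small calibration cluster: restrict to the canonical predictor set
      cands <- intersect(core_predictors(), predictors)
      des <- build_design(s, p, cands)
    }
    if (nrow(des) < length(cands) + 5) {
      warn(paste0("cluster ", k,
                  ": too few design rows to fit a model; skipped"))
      return(NULL)
    }
    nfolds_needed <- nrow(des) >= 30
    if (method == "stepwise_ml") fit_stepwise_ml(des, cands,
                                                 cluster_id = k, ...)
    else fit_penalized(des, cands, method = method, cluster_id = k,
                       nfolds = if (nfolds_needed) 10 else 3, ...)
  })
  names(fits) <- as.character(ks)
  structure(fits[!vapply(fits, is.null, logical(1))], class = "vlab_fits")
}

#' @export
print.vlab_fits <- function(x, ...) {
  cat("<vlab_fits> ", length(x), " cluster models\n", sep = "")
  for (f in x) print(f)
  invisible(x)
}

#' @describeIn fit_cluster_models All coefficients, one row per term.
#' @param x A `vlab_fits` list.
#' @param ... Unused.
#' @export
#' @method tidy vlab_fits
tidy.vlab_fits <- function(x, ...) bind_rows(lapply(unclass(x), tidy))

#' @describeIn fit_cluster_models Per-cluster fit metrics.
#' @export
#' @method glance vlab_fits
glance.vlab_fits <- function(x, ...) bind_rows(lapply(unclass(x), glance))

#' Validate fitted models on held-out patients
#'
#' For each cluster present in the holdout set, compares observed weekly
#' pain with model predictions: scatter R-squared, RMSE, and the two-sample
#' t-test p-value of observed vs predicted scores (large p = the predictions
#' are statistically similar to the observations). Clusters without a fitted
#' model are skipped with a warning.
#'
#' @param models A `vlab_fits` list keyed by cluster.
#' @param patients,series Holdout patients and their (imputed) series.
#' @param labels Tibble `patient_id`, `cluster` for the holdout patients.
#' @param predictors Terms needed to build the design.
#' @return Tibble: `cluster`, `n_obs`, `r2`, `rmse`, `t_p`.
#' @export
validate_holdout <- function(models, patients, series, labels,
                             predictors = core_predictors()) {
  if (!nrow(labels)) abort("holdout set is empty")
  rows <- lapply(sort(unique(labels$cluster)), function(k) {
    f <- models[[as.character(k)]]
    if (is.null(f)) {
      warn(paste0("no fitted model for cluster ", k, "; skipped"))
      return(NULL)
    }
    ids <- labels$patient_id[labels$cluster == k]
    des <- build_design(series[series$patient_id %in% ids, ],
                        patients[patients$patient_id %in% ids, ], predictors)
    if (!nrow(des)) return(NULL)
    pred <- predict_pain(f, des)
    res <- des$y - pred
    tt <- if (sd(des$y) == 0 && sd(pred) == 0) list(p.value = 1)
          else t.test(des$y, pred)
    tibble(cluster = k, n_obs = nrow(des),
           r2 = if (sd(des$y) > 0 && sd(pred) > 0) cor(des$y, pred)^2 else
             as.numeric(all(res == 0)),
           rmse = sqrt(mean(res^2)), t_p = tt$p.value)
  })
  bind_rows(rows)
}

#' Serialize / restore fitted cluster models as JSON
#'
#' Round-trip stable: term order, coefficients, tuning values and metrics
#' are preserved.
#'
#' @param models A `vlab_fits` list.
#' @param path JSON file path.
#' @return `write_models()` the path, invisibly; `read_models()` a
#'   `vlab_fits`.
#' @export
write_models <- function(models, path) {
  payload <- lapply(unclass(models), function(f) {
    list(cluster_id = f$cluster_id, method = f$method,
         terms = names(f$coefficients),
         coefficients = unname(f$coefficients),
         lambda = f$lambda, alpha = f$alpha, adjusted_r2 = f$adjusted_r2,
         r2 = f$r2, rmse = f$rmse, lr_p = f$lr_p, n = f$n)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  fits <- lapply(payload, function(f) {
    structure(
      list(cluster_id = f$cluster_id, method = f$method,
           coefficients = setNames(as.numeric(f$coefficients),
                                   as.character(f$terms)),
           lambda = f$lambda, alpha = f$alpha, adjusted_r2 = f$adjusted_r2,
           r2 = f$r2, rmse = f$rmse, lr_p = f$lr_p, n = f$n,
           selection_trace = NULL),
      class = "vlab_fit"
    )
  })
  structure(fits, class = "vlab_fits")
}
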