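# the square-root convention for neighbourhood size
k_rule <- function(n) max(1L, as.integer(round(sqrt(n))))

gower_to <- function(novel, records, variables, ranges) {
  acc <- numeric(nrow(records))
  used <- 0L
  for (v in variables) {
    x <- records[[v]]
    if (is.numeric(x) && !is.logical(x)) {
      r <- ranges[[v]]
      if (is.na(r) || r <= 0) next
      acc <- acc + pmin(1, abs(x - novel[[v]][1]) / r)
    } else {
      acc <- acc + (as.character(x) != as.character(novel[[v]][1]))
    }
    used <- used + 1L
  }
  acc / used
}

#' Assign a novel patient to a cluster
#'
#' Instance-based ensemble over the baseline clustering variables: (1) a
#' k-nearest-neighbour vote over Gower distance to the training patients,
#' with `k = round(sqrt(n_training))`; (2) fuzzy c-means memberships against
#' the cluster centroids, `u_c = 1 / sum_j (d_c / d_j)^2` (fuzzifier m = 2).
#' When the two methods agree that cluster wins; otherwise the method with
#' the higher normalised confidence (kNN vote fraction vs maximum fuzzy
#' membership) decides.
#'
#' @param novel One-row tibble with the clustering variables.
#' @param clusters Fitted `vlab_clusters`.
#' @return List: `cluster_id`, `confidence`, plus each method's verdict
#'   (`knn_cluster`, `knn_confidence`, `fuzzy_cluster`,
#'   `fuzzy_memberships`).
#' @export
assign_cluster <- function(novel, clusters) {
  stopifnot(inherits(clusters, "vlab_clusters"))
  train <- clusters$records
  vars <- clusters$variables
  for (v in vars) {
    x <- train[[v]]
    if (!(is.numeric(x) && !is.logical(x))) {
      if (!as.character(novel[[v]][1]) %in% as.character(x))
        abort(paste0("novel patient has unseen level for variable `", v, "`"))
    }
  }
  d <- gower_to(novel, train, vars, clusters$ranges)
  lab <- clusters$labels$cluster[match(train$patient_id,
                                       clusters$labels$patient_id)]
  k <- k_rule(nrow(train))
  nn <- order(d, train$patient_id)[seq_len(k)]
  votes <- table(factor(lab[nn], levels = sort(unique(lab))))
  knn_cluster <- as.integer(names(votes)[which.max(votes)])
  knn_conf <- max(votes) / k
  cent <- clusters$centroids
  dc <- vapply(seq_len(nrow(cent)), function(i) {
    gower_to(novel, cent[i, ], vars, clusters$ranges)
  }, numeric(1))
  if (any(dc == 0)) {
    u <- as.numeric(dc == 0) / sum(dc == 0)
  } else {
    u <- vapply(seq_along(dc), function(c6) 1 / sum((dc[c6] / dc)^2),
                numeric(1))
  }
  names(u) <- cent$cluster
  fuzzy_cluster <- as.integer(cent$cluster[which.max(u)])
  fuzzy_conf <- max(u)
  if (knn_cluster == fuzzy_cluster) {
    win <- knn_cluster; conf <- max(knn_conf, fuzzy_conf)
  } else if (knn_conf >= fuzzy_conf) {
    win <- knn_cluster; conf <- knn_conf
  } else {
    win <- fuzzy_cluster; conf <- fuzzy_conf
  }
  list(cluster_id = win, confidence = conf,
       knn_cluster = knn_cluster, knn_confidence = knn_conf,
       fuzzy_cluster = fuzzy_cluster, fuzzy_memberships = u)
}

#' k nearest neighbours on the evolving state
#'
#' Members are sorted by Euclidean distance between `state` and their own
#' values of the same features; distance ties are broken by patient id. `k`
#' larger than the member count is clamped with a warning.
#'
#' @param members Tibble with `patient_id` and one numeric column per state
#'   feature.
#' @param state Named numeric vector of the query state.
#' @param k Number of neighbours (>= 1).
#' @return Character vector of the `k` nearest patient ids, nearest first.
#' @export
knn_neighbors <- function(members, state, k) {
  if (nrow(members) == 0) abort("cluster has no members")
  if (k < 1) abort("`k` must be at least 1")
  if (k > nrow(members)) {
    warn("`k` exceeds cluster size; clamped")
    k <- nrow(members)
  }
  feats <- names(state)
  M <- as.matrix(members[feats])
  d <- sqrt(colSums((t(M) - state)^2))
  members$patient_id[order(d, members$patient_id)][seq_len(k)]
}

#' Draw next-week covariates from neighbour empirical distributions
#'
#' One draw per variable from the empirical distribution of the neighbours'
#' next-week values (each variable has its own PDF; no kernel smoothing).
#' An empty value set carries the current value forward with a warning.
#'
#' @param neighbor_values Named list: for each variable, the neighbours'
#'   next-week values.
#' @param current Named list of current values (used as fallback).
#' @return Named list with one sampled value per variable.
#' @export
sample_next_covariates <- function(neighbor_values, current = NULL) {
  out <- lapply(names(neighbor_values), function(v) {
    vals <- neighbor_values[[v]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warn(paste0("no neighbour values for `", v, "`; carrying current value forward"))
      return(current[[v]])
    }
    vals[sample.int(length(vals), 1)]
  })
  setNames(out, names(neighbor_values))
}

#' Draw a weekly dose from the cluster's responder dose distribution
#'
#' Doses are assigned week by week from the empirical distribution of the
#' doses taken that week by the cluster's 50%-responders; if the cluster has
#' no responders with a dose history the whole-cluster distribution is used
#' with a warning.
#'
#' @param dose_table Tibble `patient_id`, `week`, `dose_mg`, `is_responder`.
#' @param week Week to draw for.
#' @param n Number of draws.
#' @return Numeric vector of `n` doses (mg/day).
#' @export
assign_dose <- function(dose_table, week, n = 1) {
  pool <- dose_table$dose_mg[dose_table$week == week &
                               dose_table$is_responder &
                               !is.na(dose_table$dose_mg)]
  if (!length(pool)) {
    warn("no responder dose history for this week; using whole-cluster doses")
    pool <- dose_table$dose_mg[dose_table$week == week &
                                 !is.na(dose_table$dose_mg)]
  }
  if (!length(pool)) abort("no dose history available for this week")
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' Simulate the trajectory cloud of a novel patient
#'
#' Monte-Carlo microsimulation: the novel patient is assigned to a cluster
#' ([assign_cluster()]); `n_instances` virtual instances start from the
#' patient's baseline and advance week by week. Each week, every instance
#' finds its `k = round(sqrt(cluster size))` nearest cluster members on the
#' evolving (pain, PRSI) history -- standardised within cluster -- samples
#' its next-week PRSI from the neighbours' empirical values, draws a dose
#' from the cluster responders' dose distribution, and advances pain with
#' the cluster's regression, clipping to the 0--10 NRS. Lag references
#' before week 0 resolve to baseline.
#'
#' @param novel One-row tibble: clustering variables plus `baseline_pain`,
#'   `baseline_prsi`, feeling items and `age_group`.
#' @param clusters Fitted `vlab_clusters` (on the OS patients).
#' @param models A `vlab_fits` list keyed by cluster id.
#' @param series Imputed weekly series for the cluster members.
#' @param labels Membership tibble `patient_id`, `cluster` defining which
#'   patients supply neighbours per cluster (defaults to the cluster
#'   labels).
#' @param n_instances Number of virtual instances (1000 in the reference
#'   configuration).
#' @param n_weeks Simulation horizon in weeks.
#' @param seed Optional seed making the simulation fully reproducible.
#' @param assignment Optional precomputed [assign_cluster()] result.
#' @return A `vlab_sim`: trajectory matrix (`n_instances` x `n_weeks + 1`),
#'   assigned cluster and confidence, median final pain, responder fractions
#'   at the 50% and 30% thresholds, and the cloud's mean monotonicity.
#' @export
simulate_patient <- function(novel, clusters, models, series,
                             labels = NULL, n_instances = 1000,
                             n_weeks = 6, seed = NULL, assignment = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- clusters$labels
  if (is.null(assignment)) assignment <- assign_cluster(novel, clusters)
  cl <- assignment$cluster_id
  model <- models[[as.character(cl)]]
  if (is.null(model)) abort(paste0("no fitted model for cluster ", cl))
  ids <- labels$patient_id[labels$cluster == cl]
  wide <- function(col) {
    s <- series[series$patient_id %in% ids & series$week <= n_weeks, ]
    m <- tidyr::pivot_wider(s[, c("patient_id", "week", col)],
                            names_from = "week",
                            values_from = dplyr::all_of(col))
    m <- arrange(m, .data$patient_id)
    as.matrix(m[, as.character(0:n_weeks)])
  }
  ids <- sort(ids)
  Pm <- wide("pain"); Sm <- wide("prsi"); Dm <- wide("dose_mg")
  ok <- complete.cases(Pm) & complete.cases(Sm)
  if (!any(ok)) abort("no cluster members with complete series")
  Pm <- Pm[ok, , drop = FALSE]; Sm <- Sm[ok, , drop = FALSE]
  Dm <- Dm[ok, , drop = FALSE]; ids <- ids[ok]
  m <- nrow(Pm)
  k <- k_rule(m)

  # responder dose table for the weekly dose draw
  resp <- (Pm[, 1] - Pm[, n_weeks + 1]) / Pm[, 1] >= 0.5
  dose_table <- tibble(
    patient_id = rep(ids, n_weeks + 1),
    week = rep(0:n_weeks, each = m),
    dose_mg = as.numeric(Dm),
    is_responder = rep(resp, n_weeks + 1)
  )

  # within-cluster standardisation of the state features, per week
  mu_p <- colMeans(Pm); sd_p <- pmax(apply(Pm, 2, sd), 1e-9)
  mu_s <- colMeans(Sm); sd_s <- pmax(apply(Sm, 2, sd), 1e-9)

  n <- n_instances
  P <- matrix(NA_real_, n, n_weeks + 1)
  S <- matrix(NA_real_, n, n_weeks + 1)
  D <- matrix(NA_real_, n, n_weeks + 1)
  P[, 1] <- novel$baseline_pain
  S[, 1] <- novel$baseline_prsi
  D[, 1] <- 150
  fixed_vals <- c(
    age_75plus = as.numeric(novel$age_group == "75+"),
    calm_baseline = as.numeric(novel$calm_baseline),
    energy_baseline = as.numeric(novel$energy_baseline),
    sad_baseline = if ("sad_baseline" %in% names(novel))
      as.numeric(novel$sad_baseline) else 0,
    female = as.numeric(novel$gender == "F"),
    depression = as.numeric(novel$depression_history),
    gabapentin = as.numeric(novel$prior_gabapentin),
    monotherapy = as.numeric(novel$pregabalin_monotherapy),
    insulin_use = as.numeric(novel$insulin)
  )
  terms <- names(model$coefficients)
  needs_prsi <- any(grepl("^prsi_lag", terms))

  for (w in seq_len(n_weeks)) {
    cols <- seq_len(w)  # weeks 0..w-1
    Mz <- cbind(sweep(sweep(Pm[, cols, drop = FALSE], 2, mu_p[cols]), 2,
                      sd_p[cols], "/"),
                sweep(sweep(Sm[, cols, drop = FALSE], 2, mu_s[cols]), 2,
                      sd_s[cols], "/"))
    Sz <- cbind(sweep(sweep(P[, cols, drop = FALSE], 2, mu_p[cols]), 2,
                      sd_p[cols], "/"),
                sweep(sweep(S[, cols, drop = FALSE], 2, mu_s[cols]), 2,
                      sd_s[cols], "/"))
    D2 <- outer(rowSums(Sz^2), rep(1, m)) +
      outer(rep(1, n), rowSums(Mz^2)) - 2 * Sz %*% t(Mz)
    # next-week PRSI from each instance's k nearest members
    if (needs_prsi) {
      nxt <- Sm[, w + 1]
      S[, w + 1] <- vapply(seq_len(n), function(i) {
        nb <- order(D2[i, ], ids)[seq_len(k)]
        vals <- nxt[nb]
        vals[sample.int(length(vals), 1)]
      }, numeric(1))
    } else {
      S[, w + 1] <- S[, w]
    }
    D[, w + 1] <- assign_dose(dose_table, w, n = n)
    lagv <- function(M, lag) M[, max(w - lag, 0) + 1]
    vals <- lapply(terms, function(tm) {
      mm <- regmatches(tm, regexec("^(pain|prsi|dose)_lag([0-9]+)$", tm))[[1]]
      if (length(mm)) {
        lag <- as.integer(mm[3])
        switch(mm[2],
               pain = lagv(P, lag),
               prsi = if (lag == 0) S[, w + 1] else lagv(S, lag),
               dose = lagv(D, lag))
      } else {
        rep(fixed_vals[[tm]], n)
      }
    })
    mu <- if (length(terms))
      as.numeric(do.call(cbind, vals) %*% model$coefficients) else rep(0, n)
    P[, w + 1] <- pmin(10, pmax(0, mu))
  }

  p0 <- P[, 1]; pf <- P[, n_weeks + 1]
  pct <- (p0 - pf) / p0
  mono <- apply(P, 1, trajectory_monotonicity)
  structure(
    list(novel = novel, assigned_cluster = cl,
         confidence = assignment$confidence, assignment = assignment,
         n_instances = n, weeks = 0:n_weeks, trajectories = P,
         median_final_pain = median(pf),
         responder_fraction_50 = mean(pct >= 0.5),
         responder_fraction_30 = mean(pct >= 0.3),
         cloud_monotonicity = mean(mono)),
    class = "vlab_sim"
  )
}

#' @export
print.vlab_sim <- function(x, ...) {
  cat("<vlab_sim> cluster ", x$assigned_cluster, " (confidence ",
      sprintf("%.2f", x$confidence), "); ", x$n_instances,
      " instances\n  median final pain ",
      sprintf("%.2f", x$median_final_pain), "; responders 50%/30%: ",
      sprintf("%.1f%% / %.1f%%", 100 * x$responder_fraction_50,
              100 * x$responder_fraction_30),
      "; cloud monotonicity ", sprintf("%.3f", x$cloud_monotonicity),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_patient Long per-instance trajectories.
#' @param x A `vlab_sim` object.
#' @param ... Unused.
#' @export
#' @method tidy vlab_sim
tidy.vlab_sim <- function(x, ...) {
  tibble(
    instance = rep(seq_len(x$n_instances), times = length(x$weeks)),
    week = rep(x$weeks, each = x$n_instances),
    pain = as.numeric(x$trajectories)
  )
}

#' @describeIn simulate_patient One-row simulation summary.
#' @export
#' @method glance vlab_sim
glance.vlab_sim <- function(x, ...) {
  tibble(assigned_cluster = x$assigned_cluster, confidence = x$confidence,
         n_instances = x$n_instances,
         median_final_pain = x$median_final_pain,
         responder_fraction_50 = x$responder_fraction_50,
         responder_fraction_30 = x$responder_fraction_30,
         cloud_monotonicity = x$cloud_monotonicity)
}

#' @describeIn simulate_patient Trajectory cloud with the median path.
#' @param object A `vlab_sim` object.
#' @export
#' @method autoplot vlab_sim
autoplot.vlab_sim <- function(object, ...) {
  df <- tidy(object)
  med <- df %>% group_by(.data$week) %>%
    summarise(pain = median(.data$pain), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$week, .data$pain,
                                   group = .data$instance)) +
    ggplot2::geom_line(alpha = 0.05) +
    ggplot2::geom_line(data = med, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::ylim(0, 10) +
    ggplot2::labs(x = "week", y = "pain score (NRS)")
}
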