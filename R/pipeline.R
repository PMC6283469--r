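#' Configuration for the end-to-end pipeline
#'
#' Defaults give the demonstration scale: a 600-patient OS and 300-patient
#' RCT pool with 100 virtual instances per simulated patient, which runs the
#' whole pipeline in minutes on one CPU. The reference configuration of the
#' original analysis corresponds to `n_os = 2642`, `n_rct = 1320`,
#' `n_instances = 1000`.
#'
#' @param n_os,n_rct Cohort sizes.
#' @param n_instances Virtual instances per simulated novel patient.
#' @param n_novel Validation patients to simulate for responder prediction.
#' @param bias_strength OS selection-bias strength passed to
#'   [inject_selection_bias()].
#' @param noise_sd Weekly pain innovation SD of the generator.
#' @param n_clusters Number of clusters.
#' @param method Regression method for the per-cluster fits.
#' @param rct_duration_split Fraction of RCT patients with 12/13-week
#'   follow-up.
#' @param seed Master seed; every stage draws from this single stream.
#' @param out_dir Optional directory to write all artifacts into.
#' @return A named list of class `vlab_config`.
#' @export
pipeline_config <- function(n_os = 600, n_rct = 300, n_instances = 100,
                            n_novel = 40, bias_strength = 0.3,
                            noise_sd = 0.4, n_clusters = 6,
                            method = "lasso", rct_duration_split = 0.711,
                            seed = 1, out_dir = NULL) {
  structure(list(n_os = n_os, n_rct = n_rct, n_instances = n_instances,
                 n_novel = n_novel, bias_strength = bias_strength,
                 noise_sd = noise_sd, n_clusters = n_clusters,
                 method = method, rct_duration_split = rct_duration_split,
                 seed = seed, out_dir = out_dir),
            class = "vlab_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ",
                 conditionMessage(e)))
  })
}

#' Run the whole virtual-lab pipeline
#'
#' Generate (or load) a cohort, impute the OS visit gaps, cluster the OS
#' patients, match the RCT pool to the clusters, fit per-cluster lagged
#' regressions on the matched (calibration) dataset, validate them on the
#' unmatched OS patients, simulate a sample of validation patients as novel
#' patients to score responder prediction (PPV/accuracy at the 50% and 30%
#' thresholds), extrapolate responder status beyond week 6 against the
#' long-duration RCT patients, and assemble study-level metrics (pairwise
#' Fisher tallies, combination coverage). Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `vlab_cohort` (bias injection and
#'   generation are then skipped).
#' @return A `vlab_report` list with every stage's outputs and a `summary`
#'   tibble of the headline numbers.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  set.seed(config$seed)
  t0 <- Sys.time()

  coh <- stage("synth", {
    if (is.null(cohort)) {
      spec <- cohort_spec(n_os = config$n_os, n_rct = config$n_rct,
                          rct_duration_split = config$rct_duration_split,
                          noise_sd = config$noise_sd)
      inject_selection_bias(generate_cohort(spec), config$bias_strength)
    } else cohort
  })
  patients <- coh$patients
  os_pat <- patients[patients$source == "OS", ]
  rct_pat <- patients[patients$source == "RCT", ]

  series <- stage("prep", interpolate_weeks(coh$series))

  clusters <- stage("cluster",
                    cluster_patients(os_pat, n_clusters = config$n_clusters))

  matchset <- stage("match", match_clusters(clusters, rct_pat))

  calib_labels <- matched_labels(matchset)
  matched_os_ids <- unique(unlist(lapply(matchset$matches,
                                         function(m) m$matched_os)))
  val_ids <- setdiff(os_pat$patient_id, matched_os_ids)
  val_labels <- clusters$labels[clusters$labels$patient_id %in% val_ids, ]

  candidates <- predictor_dictionary()$term
  fits <- stage("fit", fit_cluster_models(patients, series, calib_labels,
                                          predictors = candidates,
                                          method = config$method))

  validation <- stage("validate", {
    if (nrow(val_labels)) validate_holdout(fits, os_pat, series, val_labels,
                                           predictors = candidates)
    else tibble()
  })

  sim_out <- stage("simulate", {
    pool_ids <- val_labels$patient_id
    n_novel <- min(config$n_novel, length(pool_ids))
    chosen <- sample(pool_ids, n_novel)
    sims <- lapply(chosen, function(id) {
      novel <- os_pat[os_pat$patient_id == id, ]
      asg <- assign_cluster(novel, clusters)
      if (is.null(fits[[as.character(asg$cluster_id)]])) return(NULL)
      simulate_patient(novel, clusters, fits, series,
                       labels = calib_labels, assignment = asg,
                       n_instances = config$n_instances)
    })
    keep <- !vapply(sims, is.null, logical(1))
    sims <- sims[keep]; chosen <- chosen[keep]
    truth50 <- derive_responder(series[series$patient_id %in% chosen, ],
                                0.5, 6L)
    truth30 <- derive_responder(series[series$patient_id %in% chosen, ],
                                0.3, 6L)
    g <- bind_rows(lapply(sims, glance))
    g$patient_id <- chosen
    g$true_responder_50 <- truth50$is_responder[match(chosen,
                                                      truth50$patient_id)]
    g$true_responder_30 <- truth30$is_responder[match(chosen,
                                                      truth30$patient_id)]
    list(sims = sims, summary = g)
  })

  confusion <- stage("evaluate", bind_rows(
    confusion_summary(sim_out$summary$responder_fraction_50 > 0.5,
                      sim_out$summary$true_responder_50, 0.5),
    confusion_summary(sim_out$summary$responder_fraction_30 > 0.5,
                      sim_out$summary$true_responder_30, 0.3)
  ))

  extrap <- stage("extrapolate", {
    pool <- long_duration_pool(rct_pat, series)
    per_sim <- lapply(sim_out$sims, function(s) extrapolate_status(s, pool))
    # leave-one-out skill of the transition prediction on the pool itself
    k <- k_rule(nrow(pool) - 1)
    cats <- c("decreased_pain", "maintained", "increased_pain")
    loo <- lapply(seq_len(nrow(pool)), function(i) {
      e <- extrapolate_status(list(median_final_pain = pool$pain_week6[i],
                                   cloud_monotonicity = pool$monotonicity[i]),
                              pool[-i, ], k = k)
      list(pred = e$horizon_prediction,
           votes = e$neighbor_histogram / sum(e$neighbor_histogram))
    })
    votes <- do.call(rbind, lapply(loo, function(x) x$votes[cats]))
    colnames(votes) <- cats
    skill <- evaluate_extrapolation(
      vapply(loo, function(x) x$pred, character(1)),
      pool$transition, vote_fractions = votes)
    list(pool = pool, per_sim = per_sim, skill = skill,
         maintained_pct = 100 * mean(pool$transition == "maintained"))
  })

  fisher <- stage("fisher", {
    calib_os <- calib_labels[calib_labels$patient_id %in% matched_os_ids, ]
    vars <- c("gender", "age_group", "bmi_group", "insulin",
              "depression_history", "prior_gabapentin",
              "pregabalin_monotherapy")
    bind_rows(lapply(vars, function(v) {
      pf <- pairwise_fisher(os_pat, calib_os, v)
      tibble(variable = v, n_significant = pf$n_significant,
             n_pairs = pf$n_pairs)
    }))
  })

  coverage <- stage("coverage", bind_rows(
    mutate(combination_coverage(os_pat), dataset = "OS"),
    mutate(combination_coverage(rct_pat), dataset = "RCT"),
    mutate(combination_coverage(patients), dataset = "combined")
  ))

  match_glance <- glance(matchset)
  fit_glance <- glance(fits)
  summary <- tibble(
    n_os = nrow(os_pat), n_rct = nrow(rct_pat),
    n_matched_os = match_glance$n_matched_os,
    pct_os_matched = match_glance$pct_os_matched,
    pct_rct_matched = match_glance$pct_rct_matched,
    mean_imbalance_reduction_pct =
      match_glance$mean_imbalance_reduction_pct,
    mean_adjusted_r2 = mean(fit_glance$adjusted_r2),
    mean_rmse = mean(fit_glance$rmse),
    ppv_50 = confusion$ppv[confusion$threshold == 0.5],
    accuracy_50 = confusion$accuracy[confusion$threshold == 0.5],
    ppv_30 = confusion$ppv[confusion$threshold == 0.3],
    accuracy_30 = confusion$accuracy[confusion$threshold == 0.3],
    coverage_pct_os = coverage$pct[coverage$dataset == "OS"],
    maintained_pct = extrap$maintained_pct,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  report <- structure(
    list(config = config, cohort = coh, series = series,
         clusters = clusters, matchset = matchset,
         calibration_labels = calib_labels,
         validation_labels = val_labels, models = fits,
         validation = validation, simulations = sim_out,
         confusion = confusion, extrapolation = extrap,
         fisher = fisher, coverage = coverage, summary = summary),
    class = "vlab_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.vlab_report <- function(x, ...) {
  cat("<vlab_report>\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @describeIn run_pipeline Headline metrics as a one-row tibble.
#' @param x A `vlab_report`.
#' @param ... Unused.
#' @export
#' @method glance vlab_report
glance.vlab_report <- function(x, ...) x$summary

#' Write all pipeline artifacts to a directory
#'
#' Writes `patients.csv`, `series.csv`, `clusters.csv`, `matched.csv`,
#' `match_report.json`, `models.json`, `simulation.json`,
#' `extrapolation.json`, `report.json` and a human-readable `report.md`.
#'
#' @param report A `vlab_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(report$cohort, dir)
  utils::write.csv(report$clusters$labels, file.path(dir, "clusters.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration_labels %>% mutate(matched = TRUE),
                   file.path(dir, "matched.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(report$matchset$matches, function(m) {
      list(cluster = m$cluster_id, n_matched_os = length(m$matched_os),
           n_matched_rct = length(m$matched_rct),
           l1_before = m$l1_before, l1_after = m$l1_after,
           l1_after_weighted = m$l1_after_weighted,
           imbalance_reduction_pct = m$imbalance_reduction_pct)
    }),
    file.path(dir, "match_report.json"), auto_unbox = TRUE, digits = NA)
  write_models(report$models, file.path(dir, "models.json"))
  jsonlite::write_json(report$simulations$summary,
                       file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    lapply(report$extrapolation$per_sim, function(e) {
      list(value = e$value, category = e$category,
           prediction = e$horizon_prediction,
           histogram = as.list(e$neighbor_histogram))
    }),
    file.path(dir, "extrapolation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(report$summary), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c(
    "# Virtual-lab pipeline report", "",
    sprintf("- OS patients: %d; RCT patients: %d", report$summary$n_os,
            report$summary$n_rct),
    sprintf("- OS matched: %.1f%%; mean L1 imbalance reduction: %.1f%%",
            report$summary$pct_os_matched,
            report$summary$mean_imbalance_reduction_pct),
    sprintf("- Mean adjusted R²: %.3f; mean RMSE: %.3f",
            report$summary$mean_adjusted_r2, report$summary$mean_rmse),
    sprintf("- PPV / accuracy at 50%%: %.1f%% / %.1f%%",
            100 * report$summary$ppv_50, 100 * report$summary$accuracy_50),
    sprintf("- PPV / accuracy at 30%%: %.1f%% / %.1f%%",
            100 * report$summary$ppv_30, 100 * report$summary$accuracy_30),
    sprintf("- OS combination coverage: %.1f%% of %d",
            report$summary$coverage_pct_os,
            report$coverage$n_possible[1]),
    sprintf("- Long-duration patients maintaining responder status: %.1f%%",
            report$summary$maintained_pct)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
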