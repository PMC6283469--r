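test_that("neighbourhood size follows the square-root convention", {
  expect_equal(painvlab:::k_rule(431), 21L)  # round(sqrt(431)) = round(20.76)
  expect_equal(painvlab:::k_rule(100), 10L)
  expect_equal(painvlab:::k_rule(2), 1L)
})

test_that("knn_neighbors orders by distance with id tie-breaks and clamps k", {
  members <- tibble::tibble(patient_id = c("e", "d", "c", "b", "a"),
                            x = c(5, 4, 3, 2, 1))
  # query at one end of the line: order equals coordinate order
  expect_equal(knn_neighbors(members, c(x = 0), 5),
               c("a", "b", "c", "d", "e"))
  # exact hit ranks first
  expect_equal(knn_neighbors(members, c(x = 4), 1), "d")
  # ties broken by patient id
  expect_equal(knn_neighbors(members, c(x = 2.5), 2), c("b", "c"))
  expect_warning(nn <- knn_neighbors(members, c(x = 0), 10), "clamped")
  expect_length(nn, 5)
  expect_error(knn_neighbors(members, c(x = 0), 0), "at least 1")
})

test_that("a novel patient at a centroid is assigned there with membership 1", {
  coh <- small_cohort(n_os = 240, n_rct = 0, seed = 41, separation = 1)
  cl <- cluster_patients(coh$patients, n_clusters = 6)
  cent <- cl$centroids
  novel <- cent[1, clustering_variables()]
  novel$patient_id <- "novel"
  asg <- assign_cluster(novel, cl)
  expect_equal(asg$fuzzy_cluster, cent$cluster[1])
  expect_equal(max(asg$fuzzy_memberships), 1)
  expect_equal(asg$cluster_id, cent$cluster[1])
})

test_that("a patient inside a separated cluster is assigned consistently", {
  coh <- small_cohort(n_os = 240, n_rct = 0, seed = 43, separation = 1)
  cl <- cluster_patients(coh$patients, n_clusters = 6)
  # pick the member closest to its own centroid in a large cluster
  big <- as.integer(names(which.max(table(cl$labels$cluster))))
  ids <- cl$labels$patient_id[cl$labels$cluster == big]
  cent <- cl$centroids[cl$centroids$cluster == big, ]
  recs <- cl$records[cl$records$patient_id %in% ids, ]
  d <- vapply(seq_len(nrow(recs)), function(i) {
    gower_distance(recs[i, ], cent, ranges = cl$ranges)
  }, numeric(1))
  novel <- recs[which.min(d), ]
  asg <- assign_cluster(novel, cl)
  expect_equal(asg$knn_cluster, big)
  expect_equal(asg$fuzzy_cluster, big)
  expect_equal(asg$cluster_id, big)
})

test_that("equidistant centroids give uniform fuzzy memberships", {
  # six training blocks, each differing from the novel patient on exactly
  # one distinct dichotomous variable -> all centroid distances equal
  flip <- list(
    function(p) dplyr::mutate(p, gender = "F"),
    function(p) dplyr::mutate(p, insulin = TRUE),
    function(p) dplyr::mutate(p, depression_history = TRUE),
    function(p) dplyr::mutate(p, prior_gabapentin = TRUE),
    function(p) dplyr::mutate(p, pregabalin_monotherapy = FALSE),
    function(p) dplyr::mutate(p, baseline_prsi = 15)
  )
  blocks <- lapply(1:6, function(i) flip[[i]](toy_patients(4)))
  train <- dplyr::bind_rows(blocks)
  train$patient_id <- sprintf("Q%03d", 1:24)
  labels <- tibble::tibble(patient_id = train$patient_id,
                           cluster = rep(1:6, each = 4))
  model <- structure(
    list(variables = clustering_variables(),
         ranges = c(age_years = 40, bmi_kg_m2 = 10, baseline_pain = 6,
                    baseline_prsi = 10),
         labels = labels, records = train, n_clusters = 6),
    class = "vlab_clusters"
  )
  model$centroids <- assign_centroids(model)
  novel <- toy_patients(1)
  asg <- assign_cluster(novel, model)
  expect_equal(unname(asg$fuzzy_memberships), rep(1 / 6, 6),
               tolerance = 1e-12)
  novel_bad <- dplyr::mutate(novel, gender = "X")
  expect_error(assign_cluster(novel_bad, model), "gender")
})

test_that("covariate sampling follows the neighbour empirical distribution", {
  # degenerate PDF
  expect_equal(sample_next_covariates(list(prsi = rep(4, 8)))$prsi, 4)
  # long-run mean of {2,2,6,6} is 4
  set.seed(5)
  draws <- replicate(4000, sample_next_covariates(list(p = c(2, 2, 6, 6)))$p)
  expect_equal(mean(draws), 4, tolerance = 0.15)
  expect_setequal(unique(draws), c(2, 6))
  # empty set carries the current value forward with a warning
  expect_warning(
    got <- sample_next_covariates(list(p = numeric(0)), current = list(p = 7)),
    "carrying")
  expect_equal(got$p, 7)
  # fixed seed reproducibility
  set.seed(9); a <- replicate(50, sample_next_covariates(list(p = 1:5))$p)
  set.seed(9); b <- replicate(50, sample_next_covariates(list(p = 1:5))$p)
  expect_identical(a, b)
})

test_that("weekly dose is drawn from the responders' dose distribution", {
  dt <- tibble::tibble(
    patient_id = rep(c("a", "b", "c"), each = 3),
    week = rep(0:2, 3),
    dose_mg = c(150, 300, 300, 150, 300, 300, 150, 150, 150),
    is_responder = rep(c(TRUE, TRUE, FALSE), each = 3)
  )
  expect_equal(unique(replicate(20, assign_dose(dt, 2))), 300)
  dt2 <- dt
  dt2$dose_mg[dt2$patient_id == "b"] <- 150
  set.seed(3)
  draws <- assign_dose(dt2, 2, n = 2000)
  expect_equal(mean(draws == 300), 0.5, tolerance = 0.05)
  dt3 <- dt[!dt$is_responder | dt$patient_id != "a", ]
  dt3$is_responder <- FALSE
  expect_warning(d <- assign_dose(dt3, 1), "whole-cluster")
  expect_true(d %in% c(150, 300))
})

test_that("the degenerate simulation collapses to the recursive equation", {
  ids <- sprintf("M%02d", 1:6)
  # all members share one declining trajectory (responders) and one dose
  member_pain <- c(6, 5, 4, 3.2, 2.8, 2.4, 2)
  series <- toy_series(ids, pain = member_pain, prsi = 5, dose = 300)
  labels <- tibble::tibble(patient_id = ids, cluster = 1L)
  novel <- toy_patients(1, baseline_pain = 6, baseline_prsi = 5,
                        calm_baseline = 3L)
  sim <- simulate_patient(novel, clusters = NULL, models = reference_fits(),
                          series = series, labels = labels,
                          n_instances = 100, seed = 7,
                          assignment = list(cluster_id = 1L, confidence = 1))
  # every instance identical
  expect_equal(max(apply(sim$trajectories, 2, function(x) diff(range(x)))), 0)
  # oracle: recursive cluster-1 arithmetic with sampled PRSI = 5,
  # dose history 150 at week 0 then 300, lags clamped to baseline
  p <- numeric(7); p[1] <- 6
  dose <- c(150, rep(300, 6))
  for (w in 1:6) {
    l3 <- max(w - 3, 0) + 1
    p[w + 1] <- min(10, max(0,
      0.6229 * p[w] + 0.2461 * 5 + 0.0002 * dose[l3] + 0.0354 * 3))
  }
  expect_equal(unname(sim$trajectories[1, ]), p, tolerance = 1e-10)
  expect_equal(sim$median_final_pain, p[7])
})

test_that("simulation is reproducible and threshold-monotone", {
  coh <- small_cohort(n_os = 0, n_rct = 60, seed = 47,
                      rct_duration_split = 0)
  labels <- tibble::tibble(patient_id = coh$patients$patient_id,
                           cluster = coh$patients$true_cluster)
  novel <- coh$patients[3, ]
  args <- list(novel = novel, clusters = NULL, models = reference_fits(),
               series = coh$series, labels = labels, n_instances = 150,
               assignment = list(cluster_id = novel$true_cluster,
                                 confidence = 1))
  s1 <- do.call(simulate_patient, c(args, seed = 101))
  s2 <- do.call(simulate_patient, c(args, seed = 101))
  expect_identical(s1$trajectories, s2$trajectories)
  expect_gte(s1$responder_fraction_30, s1$responder_fraction_50)
  expect_true(all(s1$trajectories >= 0 & s1$trajectories <= 10))
  finals <- s1$trajectories[, 7]
  expect_gte(s1$median_final_pain, min(finals))
  expect_lte(s1$median_final_pain, max(finals))
  s3 <- do.call(simulate_patient, c(args, seed = 202))
  expect_false(identical(s1$trajectories, s3$trajectories))
})
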