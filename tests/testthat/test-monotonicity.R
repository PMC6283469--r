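test_that("monotonicity matches the mean step sign definition", {
  expect_equal(trajectory_monotonicity(7:1), -1)
  expect_equal(trajectory_monotonicity(1:7), 1)
  expect_equal(trajectory_monotonicity(rep(5, 7)), 0)
  # hand case: signs (-1, +1, -1, +1, -1, -1) / 6
  expect_equal(trajectory_monotonicity(c(6, 5, 6, 5, 6, 5, 4)), -1 / 3)
  expect_error(trajectory_monotonicity(5), "two")
})

test_that("monotonicity is antisymmetric and affine-invariant", {
  set.seed(61)
  # enumerated small trajectories plus random ones, against a loop oracle
  oracle <- function(x) {
    s <- 0
    for (i in seq_len(length(x) - 1)) s <- s + sign(x[i + 1] - x[i])
    s / (length(x) - 1)
  }
  grids <- expand.grid(a = 0:2, b = 0:2, c = 0:2, d = 0:2)
  for (i in seq_len(nrow(grids))) {
    x <- as.numeric(grids[i, ])
    expect_equal(trajectory_monotonicity(x), oracle(x))
    expect_equal(trajectory_monotonicity(rev(x)),
                 -trajectory_monotonicity(x))
  }
  for (i in 1:20) {
    x <- stats::runif(7, 0, 10)
    expect_equal(trajectory_monotonicity(2.5 * x + 1),
                 trajectory_monotonicity(x))
    expect_equal(trajectory_monotonicity(rev(x)),
                 -trajectory_monotonicity(x))
  }
})

test_that("classification respects the inclusive +/-0.2 boundaries", {
  expect_equal(classify_monotonicity(-0.5), "below_negative")
  expect_equal(classify_monotonicity(0.2), "between")
  expect_equal(classify_monotonicity(-0.2), "between")
  expect_equal(classify_monotonicity(0.21), "above_positive")
  # exhaustive three-way partition
  vals <- seq(-1, 1, by = 0.01)
  cats <- classify_monotonicity(vals)
  expect_setequal(unique(cats),
                  c("below_negative", "between", "above_positive"))
  expect_false(anyNA(cats))
  expect_error(classify_monotonicity(1.5))
})

make_pool <- function(n, pain6, mono, transition) {
  tibble::tibble(
    patient_id = sprintf("L%03d", seq_len(n)),
    pain_week6 = pain6, monotonicity = mono,
    status6 = transition != "decreased_pain",
    status_end = transition == "decreased_pain" |
      transition == "maintained",
    transition = transition
  )
}

test_that("extrapolation follows the neighbour majority with tie -> maintained", {
  pool <- make_pool(9, pain6 = 3, mono = -0.8,
                    transition = rep("maintained", 9))
  sim <- list(median_final_pain = 3, cloud_monotonicity = -0.8)
  e <- extrapolate_status(sim, pool, k = 9)
  expect_equal(e$horizon_prediction, "maintained")
  expect_equal(unname(e$neighbor_histogram["maintained"]), 9L)
  expect_equal(sum(e$neighbor_histogram), e$k)

  pool2 <- make_pool(10, pain6 = c(rep(3, 9), 9), mono = -0.8,
                     transition = c(rep("decreased_pain", 7),
                                    rep("maintained", 2), "increased_pain"))
  e2 <- extrapolate_status(sim, pool2, k = 10)
  expect_equal(e2$horizon_prediction, "decreased_pain")
  expect_false(e2$tie)

  pool3 <- make_pool(10, pain6 = 3, mono = -0.8,
                     transition = rep(c("decreased_pain", "increased_pain"),
                                      5))
  e3 <- extrapolate_status(sim, pool3, k = 10)
  expect_true(e3$tie)
  expect_equal(e3$horizon_prediction, "maintained")
})

test_that("neighbour selection matches a brute-force distance oracle", {
  set.seed(67)
  pool <- make_pool(60, pain6 = stats::runif(60, 0, 10),
                    mono = stats::runif(60, -1, 1),
                    transition = sample(c("decreased_pain", "maintained",
                                          "increased_pain"), 60, TRUE))
  sim <- list(median_final_pain = 4.2, cloud_monotonicity = -0.5)
  k <- 8
  e <- extrapolate_status(sim, pool, k = k)
  d <- sqrt((pool$pain_week6 - 4.2)^2 + (pool$monotonicity + 0.5)^2)
  nb <- pool$transition[order(d, pool$patient_id)[1:k]]
  oracle_hist <- table(factor(nb, levels = c("decreased_pain", "maintained",
                                             "increased_pain")))
  expect_equal(unname(e$neighbor_histogram), as.integer(oracle_hist))
})

test_that("a pool with region-determined transitions is predicted above chance", {
  set.seed(71)
  n <- 120
  mono <- stats::runif(n, -1, 1)
  transition <- ifelse(mono < -0.3, "decreased_pain",
                       ifelse(mono > 0.3, "increased_pain", "maintained"))
  pool <- make_pool(n, pain6 = stats::runif(n, 3, 5), mono = mono,
                    transition = transition)
  preds <- vapply(seq_len(n), function(i) {
    extrapolate_status(list(median_final_pain = pool$pain_week6[i],
                            cloud_monotonicity = pool$monotonicity[i]),
                       pool[-i, ], k = 7)$horizon_prediction
  }, character(1))
  acc <- evaluate_extrapolation(preds, pool$transition)$accuracy
  expect_true(all(acc$accuracy > 1 / 3, na.rm = TRUE))
})

test_that("extrapolation evaluation yields exact metrics in edge cases", {
  truths <- c(rep("decreased_pain", 4), rep("maintained", 4),
              rep("increased_pain", 4))
  votes <- matrix(0, 12, 3,
                  dimnames = list(NULL, c("decreased_pain", "maintained",
                                          "increased_pain")))
  for (i in 1:12) votes[i, truths[i]] <- 1
  out <- evaluate_extrapolation(truths, truths, vote_fractions = votes)
  expect_true(all(out$accuracy$accuracy == 1))
  expect_true(all(out$roc$auc == 1))
  # categories absent from the truths are reported as missing
  out2 <- evaluate_extrapolation(rep("maintained", 3), rep("maintained", 3))
  expect_true(is.na(out2$accuracy$accuracy[
    out2$accuracy$category == "decreased_pain"]))
  expect_error(evaluate_extrapolation("a", c("a", "b")), "equal length")
})

test_that("ROC construction passes through a single threshold's operating point", {
  skip_if_not_installed("pROC")
  set.seed(73)
  n <- 200
  truth <- sample(c(TRUE, FALSE), n, TRUE)
  score <- stats::runif(n) + 0.35 * truth
  truths <- ifelse(truth, "maintained", "increased_pain")
  votes <- matrix(0, n, 3, dimnames = list(NULL, c("decreased_pain",
                                                   "maintained",
                                                   "increased_pain")))
  votes[, "maintained"] <- score
  votes[, "increased_pain"] <- 1 - score
  out <- evaluate_extrapolation(rep("maintained", n), truths,
                                vote_fractions = votes)
  roc <- out$roc[out$roc$category == "maintained", ]
  # operating point of the classifier score >= 0.5
  pred <- score >= 0.5
  tpr <- sum(pred & truth) / sum(truth)
  fpr <- sum(pred & !truth) / sum(!truth)
  # the curve thresholds include every observed score, so the classifier's
  # operating point lies exactly on the curve
  hit <- any(abs(roc$tpr - tpr) < 1e-12 & abs(roc$fpr - fpr) < 1e-12)
  expect_true(hit)
  # AUC agrees with an independent ROC implementation
  auc_oracle <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                               direction = "<")))
  expect_equal(roc$auc[1], auc_oracle, tolerance = 1e-9)
})
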