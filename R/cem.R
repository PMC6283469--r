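#' Default coarsening scheme for exact matching
#'
#' Coarsens the nine clustering variables to the categorical resolution used
#' for subgroup profiling: the five dichotomous variables enter as-is, age is
#' binned into the four age cohorts, BMI into normal/overweight/obese,
#' baseline pain into moderate (4--6) vs severe (7--10), and baseline PRSI
#' into mild (0--3) / moderate (4--6) / severe (7--10).
#'
#' @return Named list of coarsening functions; each maps a patient tibble to
#'   a character vector of levels.
#' @export
default_coarsening <- function() {
  bin_checked <- function(x, f, var) {
    out <- suppressWarnings(f(x))
    if (anyNA(out))
      abort(paste0("value outside all coarsening bins for variable `", var, "`"))
    out
  }
  list(
    gender = function(p) as.character(p$gender),
    age_group = function(p) bin_checked(p$age_years, age_group_of, "age"),
    bmi_group = function(p) bin_checked(p$bmi_kg_m2, bmi_group_of, "bmi"),
    insulin = function(p) as.character(p$insulin),
    depression = function(p) as.character(p$depression_history),
    gabapentin = function(p) as.character(p$prior_gabapentin),
    monotherapy = function(p) as.character(p$pregabalin_monotherapy),
    pain_cat = function(p) bin_checked(p$baseline_pain, pain_category_of,
                                       "baseline_pain"),
    prsi_cat = function(p) bin_checked(p$baseline_prsi, prsi_category_of,
                                       "baseline_prsi")
  )
}

#' Coarsen patients to stratum signatures
#'
#' Every patient maps to exactly one signature: the tuple of coarsened levels
#' joined with `"|"`. Patients identical after coarsening share a signature
#' regardless of their raw values.
#'
#' @param records Patient tibble.
#' @param scheme Coarsening scheme (see [default_coarsening()]).
#' @return Character vector of signatures, one per row of `records`.
#' @export
coarsen <- function(records, scheme = default_coarsening()) {
  cols <- lapply(names(scheme), function(v) scheme[[v]](records))
  do.call(paste, c(cols, sep = "|"))
}

#' Multivariate L1 imbalance between two groups
#'
#' Half the sum of absolute differences between the two groups' relative
#' frequencies over coarsened strata: 0 for identical composition, 1 for
#' fully disjoint strata. Optional per-patient weights give the weighted
#' (CEM-weighted) variant.
#'
#' @param group_a,group_b Patient tibbles (both nonempty).
#' @param scheme Coarsening scheme.
#' @param weights_a,weights_b Optional nonnegative per-patient weights.
#' @return A number in `[0, 1]`.
#' @examples
#' # identical composition
#' p <- tibble::tibble(gender = c("F", "M"), age_years = c(50, 70),
#'                     bmi_kg_m2 = c(24, 31), insulin = c(TRUE, FALSE),
#'                     depression_history = FALSE, prior_gabapentin = FALSE,
#'                     pregabalin_monotherapy = TRUE, baseline_pain = c(5, 8),
#'                     baseline_prsi = c(3, 7))
#' l1_imbalance(p, p)
#' @export
l1_imbalance <- function(group_a, group_b, scheme = default_coarsening(),
                         weights_a = NULL, weights_b = NULL) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    abort("both groups must be nonempty to compute L1 imbalance")
  sa <- coarsen(group_a, scheme); sb <- coarsen(group_b, scheme)
  if (is.null(weights_a)) weights_a <- rep(1, nrow(group_a))
  if (is.null(weights_b)) weights_b <- rep(1, nrow(group_b))
  strata <- union(sa, sb)
  fa <- vapply(strata, function(s) sum(weights_a[sa == s]), numeric(1))
  fb <- vapply(strata, function(s) sum(weights_b[sb == s]), numeric(1))
  sum(abs(fa / sum(fa) - fb / sum(fb))) / 2
}

#' Coarsened exact matching of an RCT pool to one OS cluster
#'
#' Strata are built over the union of the cluster's OS members and the RCT
#' pool; patients in strata containing both groups are retained. The matched
#' RCT patients receive the usual CEM weights that equalise the stratum
#' composition of the two matched groups. L1 imbalance is reported before
#' matching (full pool) and after, both unweighted and weighted; the
#' headline `imbalance_reduction_pct` uses the unweighted matched-set L1
#' (the weighted L1 is zero by construction when matching and imbalance
#' strata coincide, and is reported for completeness).
#'
#' @param os_members OS patients of one cluster (>= 1 row).
#' @param rct_pool Candidate RCT patients; the same RCT patient may match
#'   several clusters when matching is run cluster by cluster.
#' @param scheme Coarsening scheme.
#' @param cluster_id Optional id recorded in the result.
#' @return A `vlab_match` object.
#' @export
match_cluster <- function(os_members, rct_pool, scheme = default_coarsening(),
                          cluster_id = NA_integer_) {
  if (nrow(os_members) < 1) abort("cluster must have at least one OS member")
  s_os <- coarsen(os_members, scheme)
  s_rct <- coarsen(rct_pool, scheme)
  common <- intersect(unique(s_os), unique(s_rct))
  in_os <- s_os %in% common
  in_rct <- s_rct %in% common
  l1_before <- l1_imbalance(os_members, rct_pool, scheme)
  if (!length(common)) {
    warn(paste0("cluster ", cluster_id,
                ": no common strata between OS and RCT; empty match"))
    l1_after <- l1_after_weighted <- NA_real_
    weights_rct <- numeric(0)
  } else {
    mos <- os_members[in_os, ]; mrct <- rct_pool[in_rct, ]
    smos <- s_os[in_os]; smrct <- s_rct[in_rct]
    # CEM weights: RCT patient in stratum s gets (n_os_s / N_os) / (n_rct_s / N_rct)
    n_os_s <- table(smos); n_rct_s <- table(smrct)
    weights_rct <- as.numeric((n_os_s[smrct] / nrow(mos)) /
                                (n_rct_s[smrct] / nrow(mrct)))
    l1_after <- l1_imbalance(mos, mrct, scheme)
    l1_after_weighted <- l1_imbalance(mos, mrct, scheme,
                                      weights_b = weights_rct)
  }
  strata <- lapply(common, function(s) {
    list(os = os_members$patient_id[s_os == s],
         rct = rct_pool$patient_id[s_rct == s])
  })
  names(strata) <- common
  structure(
    list(cluster_id = cluster_id, strata = strata,
         matched_os = os_members$patient_id[in_os],
         matched_rct = rct_pool$patient_id[in_rct],
         rct_weights = setNames(weights_rct, rct_pool$patient_id[in_rct]),
         l1_before = l1_before, l1_after = l1_after,
         l1_after_weighted = l1_after_weighted,
         imbalance_reduction_pct =
           if (is.na(l1_after) || l1_before == 0) NA_real_
           else 100 * (l1_before - l1_after) / l1_before),
    class = "vlab_match"
  )
}

#' @export
print.vlab_match <- function(x, ...) {
  cat("<vlab_match> cluster ", x$cluster_id, ": ", length(x$matched_os),
      " OS + ", length(x$matched_rct), " RCT matched in ",
      length(x$strata), " strata; L1 ",
      sprintf("%.3f -> %.3f", x$l1_before, x$l1_after), "\n", sep = "")
  invisible(x)
}

#' @describeIn match_cluster Per-stratum membership counts.
#' @param x A `vlab_match` object.
#' @param ... Unused.
#' @export
#' @method tidy vlab_match
tidy.vlab_match <- function(x, ...) {
  tibble(
    cluster = x$cluster_id,
    stratum = names(x$strata),
    n_os = vapply(x$strata, function(s) length(s$os), integer(1)),
    n_rct = vapply(x$strata, function(s) length(s$rct), integer(1))
  )
}

#' @describeIn match_cluster One-row matching summary.
#' @export
#' @method glance vlab_match
glance.vlab_match <- function(x, ...) {
  tibble(cluster = x$cluster_id,
         n_matched_os = length(x$matched_os),
         n_matched_rct = length(x$matched_rct),
         n_strata = length(x$strata),
         l1_before = x$l1_before, l1_after = x$l1_after,
         l1_after_weighted = x$l1_after_weighted,
         imbalance_reduction_pct = x$imbalance_reduction_pct)
}

#' Match the RCT pool to every OS cluster
#'
#' Runs [match_cluster()] once per cluster against the full RCT pool (an RCT
#' patient may therefore match several clusters).
#'
#' @param clusters A `vlab_clusters` model fitted on the OS patients.
#' @param rct_pool RCT patient tibble.
#' @param scheme Coarsening scheme.
#' @return A `vlab_matchset`: list of `vlab_match` plus a summary tibble.
#' @export
match_clusters <- function(clusters, rct_pool, scheme = default_coarsening()) {
  stopifnot(inherits(clusters, "vlab_clusters"))
  os <- left_join(clusters$records, clusters$labels, by = "patient_id")
  matches <- lapply(sort(unique(os$cluster)), function(k) {
    match_cluster(os[os$cluster == k, ], rct_pool, scheme, cluster_id = k)
  })
  summary <- bind_rows(lapply(matches, glance))
  structure(list(matches = matches, summary = summary,
                 n_os = nrow(os), n_rct = nrow(rct_pool)),
            class = "vlab_matchset")
}

#' Calibration membership labels from a match set
#'
#' One row per (patient, cluster) for every matched OS and RCT patient; the
#' calibration dataset for the per-cluster regressions. RCT patients matched
#' to several clusters appear once per cluster.
#'
#' @param matchset A `vlab_matchset`.
#' @return Tibble `patient_id`, `cluster`.
#' @export
matched_labels <- function(matchset) {
  stopifnot(inherits(matchset, "vlab_matchset"))
  bind_rows(lapply(matchset$matches, function(m) {
    tibble(patient_id = c(m$matched_os, m$matched_rct),
           cluster = m$cluster_id)
  }))
}

#' @export
print.vlab_matchset <- function(x, ...) {
  cat("<vlab_matchset> ", nrow(x$summary), " clusters\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn match_clusters Per-cluster matching summary.
#' @param x A `vlab_matchset` object.
#' @param ... Unused.
#' @export
#' @method tidy vlab_matchset
tidy.vlab_matchset <- function(x, ...) x$summary

#' @describeIn match_clusters Whole-cohort matching summary: distinct
#'   patients matched and mean imbalance reduction.
#' @export
#' @method glance vlab_matchset
glance.vlab_matchset <- function(x, ...) {
  os_ids <- unique(unlist(lapply(x$matches, function(m) m$matched_os)))
  rct_ids <- unique(unlist(lapply(x$matches, function(m) m$matched_rct)))
  tibble(
    n_os = x$n_os, n_rct = x$n_rct,
    n_matched_os = length(os_ids), n_matched_rct = length(rct_ids),
    pct_os_matched = 100 * length(os_ids) / x$n_os,
    pct_rct_matched = 100 * length(rct_ids) / x$n_rct,
    mean_imbalance_reduction_pct =
      mean(x$summary$imbalance_reduction_pct, na.rm = TRUE)
  )
}

#' @describeIn match_clusters L1 imbalance before/after matching, by cluster.
#' @param object A `vlab_matchset` object.
#' @export
#' @method autoplot vlab_matchset
autoplot.vlab_matchset <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            cols = c("l1_before", "l1_after"),
                            names_to = "stage", values_to = "l1")
  df$stage <- factor(df$stage, levels = c("l1_before", "l1_after"),
                     labels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$l1,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cluster", y = "multivariate L1 imbalance",
                  fill = "matching")
}
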