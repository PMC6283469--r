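#' Confusion summary for responder prediction
#'
#' Prediction follows the majority rule over a simulated cloud: a patient is
#' predicted to respond when more than half of the virtual instances
#' respond. PPV is `tp / (tp + fp)` (reported as `NA` when no positive
#' predictions are made) and accuracy `(tp + tn) / n`.
#'
#' @param predicted,truth Logical vectors of equal length.
#' @param threshold Responder threshold the labels refer to (recorded).
#' @return One-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`, `ppv`,
#'   `accuracy`.
#' @export
confusion_summary <- function(predicted, truth, threshold = 0.5) {
  if (length(predicted) != length(truth))
    abort("`predicted` and `truth` must have equal length")
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth); fn <- sum(!predicted & truth)
  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         accuracy = (tp + tn) / length(truth))
}

fisher_p <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || nrow(tab) < 2) return(1)
  tryCatch(
    fisher.test(tab, workspace = 2e7)$p.value,
    error = function(e) fisher.test(tab, simulate.p.value = TRUE,
                                    B = 2000)$p.value
  )
}

#' Pairwise Fisher's exact comparison of clusters on one variable
#'
#' For every pair of clusters, a two-sided Fisher's exact test on the 2 x L
#' contingency table of the variable's levels. Significant pairs are tallied
#' at p < 0.05 without multiplicity correction (matching the tally
#' convention of the reference analysis; 6 clusters give 15 pairs).
#'
#' @param records Patient tibble.
#' @param labels Tibble `patient_id`, `cluster`.
#' @param variable Column name of a categorical variable.
#' @return List: `pairs` (tibble `cluster_a`, `cluster_b`, `p`,
#'   `significant`), `n_significant`, `n_pairs`.
#' @export
pairwise_fisher <- function(records, labels, variable) {
  df <- left_join(labels, records, by = "patient_id")
  x <- as.character(df[[variable]])
  if (length(unique(x)) < 2)
    warn(paste0("variable `", variable, "` is constant; no significant pairs"))
  ks <- sort(unique(df$cluster))
  if (length(ks) < 2) abort("need at least 2 clusters")
  pairs <- utils::combn(ks, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sub <- df$cluster %in% c(a, b)
    tab <- table(df$cluster[sub], x[sub])
    p <- fisher_p(tab)
    tibble(cluster_a = a, cluster_b = b, p = p, significant = p < 0.05)
  })
  pairs_df <- bind_rows(rows)
  list(pairs = pairs_df, n_significant = sum(pairs_df$significant),
       n_pairs = nrow(pairs_df))
}

#' Coverage of the patient-characteristic combination space
#'
#' Enumerates the Cartesian product of gender (2) x age group (4) x BMI
#' group (3) x insulin (2) x prior gabapentin (2) x baseline pain category
#' (2) -- 192 possible combinations -- and reports how many distinct
#' combinations the records cover.
#'
#' @param records Patient tibble.
#' @param variable_spec Named list: for each variable, `levels` and a
#'   function `value(records)`; the default is the six-variable space above.
#' @return A tibble: `n_possible`, `n_observed`, `pct`.
#' @export
combination_coverage <- function(records, variable_spec = NULL) {
  if (is.null(variable_spec)) {
    variable_spec <- list(
      gender = list(levels = c("F", "M"),
                    value = function(p) as.character(p$gender)),
      age_group = list(levels = age_group_levels(),
                       value = function(p) p$age_group),
      bmi_group = list(levels = bmi_group_levels(),
                       value = function(p) p$bmi_group),
      insulin = list(levels = c("FALSE", "TRUE"),
                     value = function(p) as.character(p$insulin)),
      gabapentin = list(levels = c("FALSE", "TRUE"),
                        value = function(p) as.character(p$prior_gabapentin)),
      pain_cat = list(levels = pain_category_levels(),
                      value = function(p) pain_category_of(p$baseline_pain))
    )
  }
  n_possible <- prod(vapply(variable_spec,
                            function(v) length(v$levels), numeric(1)))
  cols <- lapply(names(variable_spec), function(nm) {
    v <- variable_spec[[nm]]
    val <- v$value(records)
    bad <- !val %in% v$levels
    if (any(bad))
      abort(paste0("unknown level `", val[bad][1], "` for variable `",
                   nm, "`"))
    val
  })
  combos <- unique(do.call(paste, c(cols, sep = "|")))
  tibble(n_possible = as.integer(n_possible),
         n_observed = length(combos),
         pct = 100 * length(combos) / n_possible)
}
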