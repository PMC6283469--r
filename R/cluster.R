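#' Hierarchical clustering of patients on mixed baseline variables
#'
#' Agglomerative clustering with a Ward-style objective applied to the Gower
#' dissimilarity matrix over the nine baseline clustering variables
#' ([clustering_variables()]). The merge history is summarised by the
#' semipartial R-squared of each join -- the share of total point scatter
#' (within-cluster sum of squared dissimilarities, as accumulated by the
#' Ward update) consumed by that merge -- which is the homogeneity
#' diagnostic used to judge a cluster-count cut. The tree is cut at
#' `n_clusters` (6 in the reference configuration).
#'
#' Ward's criterion formally assumes Euclidean geometry; pairing it with a
#' Gower matrix mirrors common practice for mixed-type clinical data, and the
#' semipartial R-squared values are normalised to sum to one over the full
#' agglomeration so they remain interpretable as proportions.
#'
#' @param records Patient tibble (typically the OS patients).
#' @param n_clusters Number of clusters to cut (>= 2).
#' @param variables Clustering variables.
#' @return A `vlab_clusters` object: linkage tree (`hclust`), per-merge
#'   `semipartial_r2`, `labels` (tibble `patient_id`, `cluster`), mixed-type
#'   `centroids`, the training `records`, Gower `ranges` and a digest of the
#'   distance matrix.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_os = 60, n_rct = 0, seed = 1))
#' cl <- cluster_patients(coh$patients, n_clusters = 3)
#' tidy(cl)
#' @export
cluster_patients <- function(records, n_clusters = 6,
                             variables = clustering_variables()) {
  if (n_clusters < 2) abort("`n_clusters` must be at least 2")
  if (nrow(records) < n_clusters)
    abort("need at least `n_clusters` records")
  ranges <- gower_ranges(records, variables)
  d <- gower_matrix(records, variables, ranges)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  merge_increase <- hc$height^2 / 2   # Ward.D2 heights encode sqrt(2 * dSS)
  spr2 <- merge_increase / sum(merge_increase)
  lab <- stats::cutree(hc, k = n_clusters)
  labels <- tibble(patient_id = records$patient_id, cluster = as.integer(lab))
  model <- structure(
    list(variables = variables, ranges = ranges,
         distance_matrix_digest = sprintf("n=%d;sum=%.8f;max=%.8f",
                                          nrow(records), sum(d), max(d)),
         linkage = hc, semipartial_r2 = spr2, n_clusters = n_clusters,
         labels = labels, records = records),
    class = "vlab_clusters"
  )
  model$centroids <- assign_centroids(model)
  model
}

#' Mixed-type cluster prototypes
#'
#' The centroid of a cluster takes the mean of each numeric variable and the
#' mode of each categorical variable (ties broken toward the lowest-sorted
#' category).
#'
#' @param model A `vlab_clusters` object.
#' @param records Optional records to profile (default: the training records).
#' @return Tibble with one row per cluster and one column per variable.
#' @export
assign_centroids <- function(model, records = NULL) {
  stopifnot(inherits(model, "vlab_clusters"))
  if (is.null(records)) records <- model$records
  df <- left_join(records, model$labels, by = "patient_id")
  if (any(is.na(df$cluster))) abort("records contain patients without labels")
  counts <- table(df$cluster)
  if (any(counts == 0)) abort("empty cluster encountered")
  mode_lowest <- function(x) {
    tab <- sort(table(x))
    names(tab)[tab == max(tab)] |> sort() |> head(1)
  }
  df %>%
    group_by(.data$cluster) %>%
    summarise(across(dplyr::all_of(model$variables), function(x) {
      if (is.numeric(x) && !is.logical(x)) mean(x) else mode_lowest(x)
    }), n = n(), .groups = "drop")
}

#' @export
print.vlab_clusters <- function(x, ...) {
  cat("<vlab_clusters> ", nrow(x$labels), " patients in ", x$n_clusters,
      " clusters (sizes ",
      paste(table(x$labels$cluster), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_patients Per-cluster summary (size and centroid).
#' @param x A `vlab_clusters` object.
#' @param ... Unused.
#' @export
#' @method tidy vlab_clusters
tidy.vlab_clusters <- function(x, ...) x$centroids

#' @describeIn cluster_patients One-row model summary.
#' @export
#' @method glance vlab_clusters
glance.vlab_clusters <- function(x, ...) {
  k <- x$n_clusters
  n <- nrow(x$labels)
  tibble(
    n_patients = n, n_clusters = k,
    # homogeneity still unexplained at the chosen cut
    spr2_last_merges = sum(tail(x$semipartial_r2, k - 1)),
    min_cluster_size = min(table(x$labels$cluster)),
    max_cluster_size = max(table(x$labels$cluster))
  )
}

#' @describeIn cluster_patients Scree plot of semipartial R-squared against
#'   the number of clusters remaining, for choosing the cut.
#' @param object A `vlab_clusters` object.
#' @export
#' @method autoplot vlab_clusters
autoplot.vlab_clusters <- function(object, ...) {
  m <- length(object$semipartial_r2)
  df <- tibble(clusters_remaining = m:1 + 0,
               semipartial_r2 = object$semipartial_r2)
  df <- df[df$clusters_remaining <= 20, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$clusters_remaining,
                                   .data$semipartial_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_clusters, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "clusters remaining before merge",
                  y = "semipartial R² of merge")
}

#' Export the linkage tree in Newick format
#'
#' @param model A `vlab_clusters` object.
#' @param file Path to write; the Newick string is also returned invisibly.
#' @export
export_linkage_newick <- function(model, file) {
  if (!requireNamespace("ape", quietly = TRUE))
    abort("the `ape` package is required for Newick export")
  phy <- ape::as.phylo(model$linkage)
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
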