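# Trajectory clustering: Ward's minimum-variance criterion on Euclidean
# distances between PST vectors, replicate-concordance filtering, and
# stable/unstable classification.

#' Cluster protein stability trajectories
#'
#' Agglomerative hierarchical clustering of trajectory vectors (one
#' dimension per chase day, ln scale) under Ward's minimum-variance
#' criterion with Euclidean distances, cut to exactly `k` clusters. All
#' trajectories must share the same chase-day grid. Clusters are labelled
#' `A`, `B`, ... in order of increasing mean member slope, so `A` is
#' always the steepest (least stable) cluster.
#'
#' @param psts Long PST tibble from [build_psts()] (any mix of scopes).
#' @param k Number of clusters, between 1 and the number of trajectories.
#' @return Object of class `quad_clusters`: list with `assignments`
#'   (tibble `group_id`, `tissue`, `scope`, `cluster`), `k`, `summaries`
#'   (per cluster and chase day: mean and SD of `ln_ratio`, member count,
#'   mean slope), `cluster_slopes` (tibble `cluster`, `mean_slope`,
#'   `n_members`), and the underlying `stats::hclust` tree.
#' @export
cluster_psts <- function(psts, k) {
  wide <- psts |>
    tidyr::pivot_wider(names_from = "chase_day", values_from = "ln_ratio")
  day_cols <- setdiff(names(wide), c("group_id", "tissue", "scope"))
  mat <- as.matrix(wide[day_cols])
  if (anyNA(mat)) {
    qp_input_error("all trajectories must share the same chase-day grid")
  }
  n <- nrow(mat)
  k <- check_count(k, "k")
  if (k > n) qp_config_error("k", "cannot exceed the number of trajectories")
  rownames(mat) <- paste(wide$group_id, wide$tissue, wide$scope, sep = "|")

  if (n == 1L) {
    member <- 1L
    hc <- NULL
  } else {
    hc <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
    member <- cutree(hc, k = k)
  }

  assignments <- tibble::tibble(
    group_id = wide$group_id,
    tissue = wide$tissue,
    scope = wide$scope,
    cluster_i = as.integer(member)
  )

  # per-trajectory slopes, then order clusters steepest-first -> letters
  slopes <- fit_kinetics(psts)
  assignments <- dplyr::left_join(
    assignments, slopes[c("group_id", "tissue", "scope", "slope")],
    by = c("group_id", "tissue", "scope"))
  means <- assignments |>
    dplyr::group_by(.data$cluster_i) |>
    dplyr::summarise(mean_slope = mean(.data$slope),
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$mean_slope)
  labels <- if (k <= 26L) LETTERS[seq_len(k)] else sprintf("C%03d", seq_len(k))
  means$cluster <- labels
  assignments <- assignments |>
    dplyr::left_join(means[c("cluster_i", "cluster")], by = "cluster_i") |>
    dplyr::select(-"cluster_i")

  summaries <- psts |>
    dplyr::left_join(
      assignments[c("group_id", "tissue", "scope", "cluster")],
      by = c("group_id", "tissue", "scope")) |>
    dplyr::group_by(.data$cluster, .data$chase_day) |>
    dplyr::summarise(
      mean_ln_ratio = mean(.data$ln_ratio),
      sd_ln_ratio = stats::sd(.data$ln_ratio),
      n_members = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(
      assignments = assignments[c("group_id", "tissue", "scope",
                                  "cluster", "slope")],
      k = k,
      summaries = summaries,
      cluster_slopes = means[c("cluster", "mean_slope", "n_members")],
      tree = hc
    ),
    class = "quad_clusters"
  )
}

#' @export
print.quad_clusters <- function(x, ...) {
  cat(sprintf("Trajectory clustering: %d trajectories in %d cluster(s)\n",
              nrow(x$assignments), x$k))
  print(x$cluster_slopes)
  invisible(x)
}

#' Replicate-concordance filter
#'
#' A protein's trajectories are trusted only if every biological
#' replicate falls in the same cluster. Groups whose per-replicate PSTs
#' all share one cluster label are kept; groups with discordant
#' replicates are dropped. Groups represented by a single replicate are
#' kept but flagged `untested`. Dropping a group never changes other
#' groups' labels (no re-clustering).
#'
#' @param clusters A `quad_clusters` object built from per-replicate PSTs.
#' @return List with `kept` and `dropped` (character vectors of
#'   `group_id`), and `table` (per group and tissue: `n_replicates`,
#'   `concordant`, `untested`).
#' @export
concordance_filter <- function(clusters) {
  stopifnot(inherits(clusters, "quad_clusters"))
  tab <- clusters$assignments |>
    dplyr::group_by(.data$group_id, .data$tissue) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      concordant = dplyr::n_distinct(.data$cluster) == 1L,
      .groups = "drop"
    ) |>
    dplyr::mutate(untested = .data$n_replicates == 1L)
  list(
    kept = tab$group_id[tab$concordant],
    dropped = tab$group_id[!tab$concordant],
    table = tab
  )
}

#' Classify clusters (and their proteins) as stable or unstable
#'
#' Clusters whose mean trajectory slope is at or above the threshold are
#' labelled `stable` (shallow decay), the rest `unstable`; each protein
#' inherits its cluster's label. The default threshold of -0.10 per day
#' sits midway between typical brain (-0.11) and liver (-0.16) mean
#' slopes; boundary inclusive toward stable.
#'
#' @param clusters A `quad_clusters` object.
#' @param slope_threshold Per-day slope threshold.
#' @return The `quad_clusters` object with `stability_class` added to
#'   `cluster_slopes` and `assignments`.
#' @export
classify_stability <- function(clusters, slope_threshold = -0.10) {
  stopifnot(inherits(clusters, "quad_clusters"))
  if (!is.numeric(slope_threshold) || length(slope_threshold) != 1L ||
      is.na(slope_threshold)) {
    qp_config_error("slope_threshold", "must be a single number")
  }
  cs <- clusters$cluster_slopes
  cs$stability_class <- ifelse(cs$mean_slope >= slope_threshold,
                               "stable", "unstable")
  clusters$cluster_slopes <- cs
  clusters$assignments <- clusters$assignments |>
    dplyr::select(-dplyr::any_of("stability_class")) |>
    dplyr::left_join(cs[c("cluster", "stability_class")], by = "cluster")
  clusters$slope_threshold <- slope_threshold
  clusters
}

#' Export the cluster merge tree in Newick format
#'
#' Writes the full agglomeration tree (merge heights as branch lengths)
#' so the cluster number can be chosen by dendrogram inspection.
#'
#' @param clusters A `quad_clusters` object with at least 2 trajectories.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_merge_tree <- function(clusters, path) {
  stopifnot(inherits(clusters, "quad_clusters"))
  if (is.null(clusters$tree)) {
    qp_input_error("merge tree requires at least two trajectories")
  }
  phy <- ape::as.phylo(clusters$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write cluster assignments
#'
#' @param clusters A `quad_clusters` object (ideally after
#'   [classify_stability()]).
#' @param concordance Optional result of [concordance_filter()]; adds a
#'   `concordant` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, concordance = NULL) {
  out <- clusters$assignments
  if (!is.null(concordance)) {
    out <- dplyr::left_join(
      out,
      concordance$table[c("group_id", "tissue", "concordant")],
      by = c("group_id", "tissue"))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
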