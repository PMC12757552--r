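#' Cluster Cys sites by oxidation profile
#'
#' Agglomerative hierarchical clustering (average linkage on Euclidean
#' distances) of site oxidation profiles across conditions or datasets,
#' cut to exactly `k` clusters. Rows with any missing entry are dropped
#' (and reported); rows are sorted by `site_key` before clustering so the
#' result is invariant to input row order, with ties broken
#' lexicographically by site key. With `standardize = TRUE` each profile
#' is z-scored first, which makes the clustering respond to profile shape
#' rather than absolute oxidation level.
#'
#' @param profiles A data frame: `site_key` plus numeric profile columns
#'   (e.g. per-condition mean oxidation %).
#' @param k Number of clusters (1 <= k <= number of usable sites).
#' @param standardize Z-score each row first.
#'
#' @return An object of class `cluster_result`: list with `assignments`
#'   (tibble `site_key`, `cluster`), `centroids` (tibble `cluster`,
#'   `n_sites`, profile columns; means over member profiles on the input
#'   scale), `dropped` (site keys removed for missingness), `tree`
#'   (the `hclust` object) and `params`.
#' @export
cluster_profiles <- function(profiles, k = 10, standardize = FALSE) {
  value_cols <- setdiff(names(profiles), "site_key")
  tbl <- dplyr::arrange(as_tibble(profiles), .data$site_key)
  m <- as.matrix(tbl[value_cols])
  rownames(m) <- tbl$site_key
  ok <- complete.cases(m)
  dropped <- tbl$site_key[!ok]
  if (length(dropped) > 0) {
    inform(sprintf("cluster_profiles: dropped %d site(s) with missing values",
                   length(dropped)))
  }
  m <- m[ok, , drop = FALSE]
  if (k < 1 || k > nrow(m)) {
    stop_usage("k (%d) must be between 1 and the number of usable sites (%d)",
               k, nrow(m))
  }
  x <- m
  if (standardize) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    s[s == 0] <- 1
    x <- (x - mu) / s
  }
  tree <- hclust(dist(x, method = "euclidean"), method = "average")
  cl <- cutree(tree, k = k)
  assignments <- tibble(site_key = rownames(m), cluster = as.integer(cl))
  centroids <- assignments |>
    dplyr::left_join(as_tibble(m, rownames = "site_key"), by = "site_key") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     dplyr::across(dplyr::all_of(value_cols), mean),
                     .groups = "drop")
  structure(
    list(assignments = assignments, centroids = centroids,
         dropped = dropped, tree = tree,
         params = list(k = k, standardize = standardize,
                       linkage = "average", metric = "euclidean")),
    class = "cluster_result"
  )
}

#' Merge clusters with similar oxidation profiles into lettered groups
#'
#' Single-linkage merging of clusters whose centroid profiles are
#' Pearson-correlated at or above a threshold: the connected components of
#' the centroid-correlation graph become groups, labelled `A`, `B`, `C`,
#' ... in order of decreasing total member count (ties broken by smallest
#' member cluster id). Because merging is single linkage, raising the
#' threshold can only split groups, never merge them.
#'
#' @param result A [cluster_profiles()] result.
#' @param min_centroid_correlation Threshold in (0, 1\] (default 0.8).
#'
#' @return The `cluster_result` with a `group` column added to
#'   `assignments` and `centroids`, and the threshold recorded in
#'   `params`.
#' @export
group_clusters <- function(result, min_centroid_correlation = 0.8) {
  stopifnot(inherits(result, "cluster_result"))
  if (min_centroid_correlation <= 0 || min_centroid_correlation > 1) {
    stop_usage("min_centroid_correlation must be in (0, 1]")
  }
  cent <- result$centroids
  value_cols <- setdiff(names(cent), c("cluster", "n_sites", "group"))
  m <- t(as.matrix(cent[value_cols]))
  k <- ncol(m)
  if (k == 1) {
    comp <- 1L
  } else {
    cors <- suppressWarnings(cor(m))
    cors[is.na(cors)] <- 0  # constant centroids correlate with nothing
    diag(cors) <- 1
    # single-linkage components of the >= threshold graph: cut the
    # single-linkage tree of d = 1 - r at height 1 - threshold
    tree <- hclust(stats::as.dist(1 - cors), method = "single")
    comp <- cutree(tree, h = 1 - min_centroid_correlation)
  }
  sizes <- tapply(cent$n_sites, comp, sum)
  firsts <- tapply(cent$cluster, comp, min)
  rank <- order(-sizes, firsts)
  letter <- character(length(sizes))
  letter[rank] <- make.unique(LETTERS[(seq_along(rank) - 1) %% 26 + 1],
                              sep = "")[seq_along(rank)]
  group_of_comp <- setNames(letter, names(sizes))
  cent$group <- group_of_comp[as.character(comp)]
  assign_group <- setNames(cent$group, cent$cluster)
  result$centroids <- cent
  result$assignments$group <-
    assign_group[as.character(result$assignments$cluster)]
  result$params$min_centroid_correlation <- min_centroid_correlation
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Oxidation-profile clustering: %d sites in %d clusters (%s linkage, %s)\n",
              nrow(x$assignments), x$params$k, x$params$linkage,
              x$params$metric))
  if ("group" %in% names(x$centroids)) {
    cat(sprintf("Groups (centroid correlation >= %.2f): %s\n",
                x$params$min_centroid_correlation,
                paste(sort(unique(x$centroids$group)), collapse = ", ")))
  }
  invisible(x)
}
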