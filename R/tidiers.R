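#' Tidy differential-oxidation results
#'
#' @param x A `diff_redox` object from [differential_oxidation()].
#' @param ... Unused.
#'
#' @return A plain tibble of the per-site records.
#' @exportS3Method generics::tidy
tidy.diff_redox <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_redox")
  attr(out, "criterion_used") <- NULL
  attr(out, "params") <- NULL
  as_tibble(out)
}

#' Summarise a differential-oxidation comparison
#'
#' @param x A `diff_redox` object.
#' @param ... Unused.
#'
#' @return A one-row tibble: tested site count, oxidized/reduced call
#'   counts, and which significance criterion was active (`"fdr"` or
#'   `"p_fallback"`).
#' @exportS3Method generics::glance
glance.diff_redox <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_oxidized = sum(x$call == "oxidized"),
    n_reduced = sum(x$call == "reduced"),
    criterion_used = attr(x, "criterion_used")
  )
}

#' @rdname tidy.diff_redox
#' @exportS3Method generics::tidy
tidy.diff_abundance <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_abundance")
  attr(out, "params") <- NULL
  as_tibble(out)
}

#' @rdname glance.diff_redox
#' @exportS3Method generics::glance
glance.diff_abundance <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2_diff > 0),
    n_down = sum(x$significant & x$log2_diff < 0)
  )
}

#' Tidy a clustering result
#'
#' @param x A `cluster_result` from [cluster_profiles()] /
#'   [group_clusters()].
#' @param ... Unused.
#'
#' @return The per-site assignment tibble (`site_key`, `cluster`, and
#'   `group` when groups have been assigned).
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) x$assignments

#' @rdname tidy.cluster_result
#' @return For `glance()`: one row per cluster with size, group label and
#'   centroid values.
#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) x$centroids

#' Tidy a distribution summary
#'
#' @param x A `distribution_summary` object.
#' @param ... Unused.
#'
#' @return The per-sample quartile/range tibble; interval counts stay in
#'   `x$counts`.
#' @exportS3Method generics::tidy
tidy.distribution_summary <- function(x, ...) x$stats

#' Tidy ANOVA + Fisher's LSD results
#'
#' @param x An `anova_lsd` object from [anova_fisher_lsd()].
#' @param ... Unused.
#'
#' @return The pairwise comparison tibble.
#' @exportS3Method generics::tidy
tidy.anova_lsd <- function(x, ...) x$pairwise

#' @rdname tidy.anova_lsd
#' @return For `glance()`: one row with the omnibus F statistic, degrees
#'   of freedom and p-value.
#' @exportS3Method generics::glance
glance.anova_lsd <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value)
}
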