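#' Volcano plot of differential oxidation
#'
#' Oxidation change against -log10 p, colored by call. The dashed guides
#' mark the minimum-change threshold used for the calls.
#'
#' @param object A `diff_redox` object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.diff_redox <- function(object, ...) {
  params <- attr(object, "params")
  df <- tidy(object)
  df <- df[!is.na(df$p_value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * params$delta_min,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(oxidized = "#c0392b",
                                            reduced = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(
      x = sprintf("oxidation change %s - %s (percentage points)",
                  params$group_b, params$group_a),
      y = expression(-log[10] ~ p), colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential abundance
#'
#' @param object A `diff_abundance` object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.diff_abundance <- function(object, ...) {
  params <- attr(object, "params")
  df <- tidy(object)
  df <- df[!is.na(df$p_value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_diff,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey70")) +
    ggplot2::labs(
      x = sprintf("log2 abundance %s - %s", params$group_b, params$group_a),
      y = expression(-log[10] ~ p), colour = sprintf("q < %g", params$q_max)
    ) +
    ggplot2::theme_minimal()
}

#' Centroid profile plot of oxidation clusters
#'
#' One line per cluster centroid across the profile columns, faceted by
#' group when groups have been assigned.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  cent <- object$centroids
  value_cols <- setdiff(names(cent), c("cluster", "n_sites", "group"))
  long <- tidyr::pivot_longer(cent, dplyr::all_of(value_cols),
                              names_to = "column", values_to = "oxidation")
  long$column <- factor(long$column, levels = value_cols)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$column,
                                          y = .data$oxidation,
                                          group = .data$cluster,
                                          colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "oxidation (%)", colour = "cluster") +
    ggplot2::theme_minimal()
  if ("group" %in% names(cent)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Histogram of per-sample oxidation distributions
#'
#' @param ox An oxidation tibble (`site_key` + sample columns).
#' @param binwidth Histogram bin width in percentage points.
#'
#' @return A ggplot object, faceted by sample.
#' @export
plot_oxidation_distribution <- function(ox, binwidth = 5) {
  long <- tidyr::pivot_longer(ox, -"site_key", names_to = "sample_id",
                              values_to = "oxidation")
  long <- long[!is.na(long$oxidation), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$oxidation)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#2c3e50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "oxidation (%)", y = "Cys peptides") +
    ggplot2::theme_minimal()
}
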