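#' Prepare a protein-abundance table: log2, valid-value filter, median
#' normalization
#'
#' The quantitative-proteomics track's preprocessing. Zero intensities are
#' treated as missing, non-missing values are log2-transformed (set
#' `already_log2 = TRUE` for exports already on log2 scale), rows with
#' fewer than `min_valid` non-missing values across all channels are
#' dropped, and channels are median-centered: each channel's median is
#' subtracted and the grand mean of the channel medians added back, so
#' every channel ends at a common location while the table keeps its
#' original scale. Median centering ignores missing values, so it commutes
#' with the valid-value filter.
#'
#' @param raw A data frame: `accession` plus one intensity column per
#'   channel (non-negative; zeros encode missing).
#' @param min_valid Minimum number of non-missing values per row, counted
#'   across all channels (default 9 of a 16-plex).
#' @param already_log2 If `TRUE`, values are taken as log2 abundances
#'   (zeros still encode missing).
#'
#' @return A tibble of log2 abundances (`accession` + channel columns,
#'   `NA` for missing). An empty result (all rows filtered) warns rather
#'   than errors.
#' @export
prepare_abundance <- function(raw, min_valid = 9, already_log2 = FALSE) {
  channel_cols <- setdiff(names(raw), "accession")
  if (min_valid > length(channel_cols)) {
    stop_usage("min_valid (%d) exceeds the number of channels (%d)",
               min_valid, length(channel_cols))
  }
  m <- as.matrix(raw[channel_cols])
  if (any(m < 0, na.rm = TRUE)) stop_data("negative intensities in abundance table")
  m[m == 0] <- NA
  if (!already_log2) m <- log2(m)

  keep <- rowSums(!is.na(m)) >= min_valid
  if (!any(keep)) warn("no proteins left after the valid-value filter")
  m <- m[keep, , drop = FALSE]

  if (nrow(m) > 0) {
    meds <- apply(m, 2, median, na.rm = TRUE)
    m <- sweep(m, 2, meds) + mean(meds)
  }
  out <- tibble(accession = raw$accession[keep])
  dplyr::bind_cols(out, as_tibble(m))
}

#' Differential protein abundance with permutation FDR
#'
#' Two-sided equal-variance t-tests on log2 abundances between two
#' conditions, corrected with the same permutation-based FDR as the redox
#' track ([permutation_fdr()]). A protein is significant when
#' `q < q_max`.
#'
#' @param abundance A prepared log2 abundance tibble
#'   (see [prepare_abundance()]).
#' @param design A design data frame with columns `channel_id`,
#'   `condition` (and optionally `replicate`) covering the abundance
#'   channels.
#' @param group_a,group_b Condition names (the log2 difference is B - A).
#' @param q_max FDR threshold (default 0.1).
#' @param n_permutations,seed Passed to [permutation_fdr()].
#'
#' @return A tibble of class `diff_abundance`: `accession`,
#'   `mean_log2_a`, `mean_log2_b`, `log2_diff`, `t_statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
differential_abundance <- function(abundance, design, group_a, group_b,
                                   q_max = 0.1, n_permutations = 1000,
                                   seed = 1L) {
  required <- c("channel_id", "condition")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop_data("abundance design is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% design$condition) stop_usage("unknown condition: %s", g)
  }
  ch_a <- intersect(design$channel_id[design$condition == group_a],
                    names(abundance))
  ch_b <- intersect(design$channel_id[design$condition == group_b],
                    names(abundance))
  if (length(ch_a) < 2 || length(ch_b) < 2) {
    stop_data("conditions '%s' and '%s' need >= 2 channels present in the table",
              group_a, group_b)
  }
  tbl <- dplyr::rename(abundance, site_key = "accession")
  labels <- setNames(rep(c("A", "B"), c(length(ch_a), length(ch_b))),
                     c(ch_a, ch_b))
  fdr <- permutation_fdr(tbl, labels, n_permutations, seed)
  m <- as.matrix(abundance[c(ch_a, ch_b)])
  mu_a <- rowMeans(m[, seq_along(ch_a), drop = FALSE], na.rm = TRUE)
  mu_b <- rowMeans(m[, -seq_along(ch_a), drop = FALSE], na.rm = TRUE)
  mu_a[!is.finite(mu_a)] <- NA_real_
  mu_b[!is.finite(mu_b)] <- NA_real_
  out <- tibble(
    accession = abundance$accession,
    mean_log2_a = mu_a, mean_log2_b = mu_b, log2_diff = mu_b - mu_a,
    t_statistic = fdr$t_statistic, p_value = fdr$p_value,
    q_value = fdr$q_value,
    significant = !is.na(fdr$q_value) & fdr$q_value < q_max
  )
  attr(out, "params") <- list(group_a = group_a, group_b = group_b,
                              q_max = q_max,
                              n_permutations = n_permutations, seed = seed)
  class(out) <- c("diff_abundance", class(out))
  out
}
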