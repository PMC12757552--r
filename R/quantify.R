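#' Normalize reporter channels within label classes
#'
#' Applies per-channel median normalization separately to the SH and Sox
#' label classes of each plex run: each channel's median of log2-transformed
#' non-zero intensities is shifted additively (on log2 scale, i.e. a
#' multiplicative correction on linear scale) to the mean of the medians of
#' its label class. Channel medians are only comparable within one
#' multiplexed run, so normalization never crosses plex runs. Zeros encode
#' missing observations: they are excluded from the medians and remain zero
#' in the output.
#'
#' @param reporter A reporter tibble as returned by [read_reporter_table()]
#'   or [simulate_redox_experiment()].
#' @param design A validated channel design.
#'
#' @return The reporter tibble with normalized intensities (linear scale).
#' @export
normalize_channels <- function(reporter, design) {
  design <- validate_channel_design(design)
  missing_channels <- setdiff(design$channel_id, names(reporter))
  if (length(missing_channels) > 0) {
    stop_data("reporter table lacks design channel column(s): %s",
              paste(missing_channels, collapse = ", "))
  }
  out <- as_tibble(reporter)
  for (grp in split(design, paste(design$plex_run, design$label_class))) {
    meds <- vapply(grp$channel_id, function(ch) {
      v <- out[[ch]]
      nz <- v > 0
      if (!any(nz)) {
        stop_data("channel '%s' has no non-zero intensities; cannot normalize", ch)
      }
      median(log2(v[nz]))
    }, numeric(1))
    target <- mean(meds)
    for (ch in grp$channel_id) {
      out[[ch]] <- out[[ch]] * 2^(target - meds[[ch]])
    }
  }
  out
}

#' Compute per-site oxidation percentages
#'
#' Converts normalized SH/Sox channel pairs to the core redox statistic:
#' for each Cys site and sample, oxidation (%) = `Sox / (SH + Sox) * 100`.
#' Zeros encode "not observed", and by default (`strict_pair_na = TRUE`)
#' any zero channel makes the pair's oxidation missing (`NA`): an
#' unobserved reporter ion carries no evidence that the site is fully
#' reduced or fully oxidized, and under channel-level dropout treating it
#' as a 0 %/100 % boundary value badly distorts replicate means and
#' variances. With `strict_pair_na = FALSE` only a zero SH + Sox sum is
#' missing, and a single zero channel yields the exact boundary value
#' 0 % (Sox unobserved) or 100 % (SH unobserved).
#'
#' @param reporter A normalized reporter tibble (see [normalize_channels()]).
#' @param design A validated channel design.
#' @param strict_pair_na If `TRUE` (default), a zero in either channel of
#'   a pair gives `NA`; if `FALSE`, a single zero gives a 0/100 boundary
#'   value and only a zero sum gives `NA`.
#'
#' @return An oxidation tibble: `site_key` plus one numeric column per
#'   sample, values in \[0, 100\] or `NA`.
#' @export
compute_oxidation <- function(reporter, design, strict_pair_na = TRUE) {
  design <- validate_channel_design(design)
  missing_channels <- setdiff(design$channel_id, names(reporter))
  if (length(missing_channels) > 0) {
    stop_data("sample channel(s) absent from reporter table: %s",
              paste(missing_channels, collapse = ", "))
  }
  chans <- sample_channels(design)
  ox <- tibble(site_key = reporter$site_key)
  for (s in names(chans)) {
    sh <- reporter[[chans[[s]][["SH"]]]]
    sox <- reporter[[chans[[s]][["Sox"]]]]
    total <- sh + sox
    val <- ifelse(total == 0, NA_real_, 100 * sox / total)
    if (strict_pair_na) val[sh == 0 | sox == 0] <- NA_real_
    # the exact value lies in [0, 100]; guard against one-ulp float spill
    ox[[s]] <- pmin(100, pmax(0, val))
  }
  ox
}

#' Filter sites by number of valid values
#'
#' Retains sites with at least `min_valid` non-missing oxidation values,
#' counted either within every condition (`scope = "per_condition"`) or
#' across all samples (`scope = "overall"`). `min_valid = 1` with
#' per-condition scope is the "at least one of three quantitative values"
#' filter used for sparse designs.
#'
#' @param ox An oxidation tibble (`site_key` + sample columns).
#' @param min_valid Non-negative integer threshold.
#' @param scope `"per_condition"` (requires `design`) or `"overall"`.
#' @param design Channel design, needed to group samples by condition.
#'
#' @return The filtered oxidation tibble. The retained/dropped counts are
#'   reported via a message.
#' @export
filter_min_valid <- function(ox, min_valid = 1,
                             scope = c("per_condition", "overall"),
                             design = NULL) {
  scope <- match.arg(scope)
  sample_cols <- setdiff(names(ox), "site_key")
  if (scope == "overall") {
    if (min_valid > length(sample_cols)) {
      stop_usage("min_valid (%d) exceeds the number of samples (%d)",
                 min_valid, length(sample_cols))
    }
    n_valid <- rowSums(!is.na(as.matrix(ox[sample_cols])))
    keep <- n_valid >= min_valid
  } else {
    if (is.null(design)) stop_usage("per_condition scope requires a design")
    st <- sample_table(validate_channel_design(design))
    st <- st[st$sample_id %in% sample_cols, , drop = FALSE]
    keep <- rep(TRUE, nrow(ox))
    for (cond_samples in split(st$sample_id, st$condition)) {
      if (min_valid > length(cond_samples)) {
        stop_usage("min_valid (%d) exceeds the replicate count (%d) of a condition",
                   min_valid, length(cond_samples))
      }
      n_valid <- rowSums(!is.na(as.matrix(ox[cond_samples])))
      keep <- keep & n_valid >= min_valid
    }
  }
  inform(sprintf("filter_min_valid: retained %d of %d sites (dropped %d)",
                 sum(keep), nrow(ox), sum(!keep)))
  ox[keep, , drop = FALSE]
}

#' Replicate coefficients of variation of oxidation values
#'
#' For every site and condition with at least two non-missing replicate
#' oxidation values, computes CV (%) = 100 * sd / mean (sample standard
#' deviation, n - 1 denominator). The per-condition median CV over sites
#' with a defined CV is the reproducibility summary reported for replicate
#' designs; retrieve it with [glance()].
#'
#' @param ox An oxidation tibble.
#' @param design A validated channel design.
#'
#' @return A tibble of class `redox_cv` with columns `site_key`,
#'   `condition`, `n_valid`, `cv_pct` (`NA` where undefined).
#' @export
replicate_cv <- function(ox, design) {
  st <- sample_table(validate_channel_design(design))
  st <- st[st$sample_id %in% names(ox), , drop = FALSE]
  res <- lapply(split(st$sample_id, st$condition), function(samples) {
    m <- as.matrix(ox[samples])
    n_valid <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1, sd, na.rm = TRUE)
    cv <- ifelse(n_valid >= 2 & mu > 0, 100 * s / mu, NA_real_)
    tibble(site_key = ox$site_key, n_valid = n_valid, cv_pct = cv)
  })
  out <- dplyr::bind_rows(res, .id = "condition") |>
    dplyr::select("site_key", "condition", "n_valid", "cv_pct") |>
    dplyr::arrange(.data$site_key, .data$condition)
  class(out) <- c("redox_cv", class(out))
  out
}

#' @rdname replicate_cv
#' @param x A `redox_cv` object.
#' @param ... Unused.
#' @return For `glance()`: one row per condition with `median_cv_pct` and
#'   the number of sites with a defined CV.
#' @exportS3Method generics::glance
glance.redox_cv <- function(x, ...) {
  x |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      median_cv_pct = median(.data$cv_pct, na.rm = TRUE),
      n_sites = sum(!is.na(.data$cv_pct)),
      .groups = "drop"
    )
}
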