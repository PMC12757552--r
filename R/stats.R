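#' Two-sided equal-variance Student's t-test
#'
#' Classic pooled-variance two-sample t-test, the per-site test of the
#' redox pipeline. Sign convention: `t = (mean(a) - mean(b)) / se`. When
#' both groups have zero variance the statistic is defined as 0 with p = 1
#' if the means agree (this keeps fully saturated 0 %/100 % sites from
#' producing spurious infinities), and as a signed infinity with p = 0 if
#' they differ. Fewer than two non-missing values in either group gives an
#' undefined (`NA`) result rather than an error.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped).
#' @param welch If `TRUE`, use the unequal-variance (Welch) test instead.
#'
#' @return A named list with elements `t`, `p`, `df`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
two_sample_t <- function(values_a, values_b, welch = FALSE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(dm) * Inf, p = 0, df = df))
  }
  t <- dm / sqrt(se2)
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Vectorized per-row pooled t statistics on a sites x samples matrix with
# NAs. Returns t with the (A - B)/se convention; NA where a group has < 2
# values; 0 where both variances and the mean difference are zero; +-Inf
# where only the variances are zero.
row_t_stats <- function(m, idx_a, idx_b) {
  ma <- m[, idx_a, drop = FALSE]
  mb <- m[, idx_b, drop = FALSE]
  na <- rowSums(!is.na(ma))
  nb <- rowSums(!is.na(mb))
  mu_a <- rowMeans(ma, na.rm = TRUE)
  mu_b <- rowMeans(mb, na.rm = TRUE)
  ss_a <- rowSums((ma - mu_a)^2, na.rm = TRUE)
  ss_b <- rowSums((mb - mu_b)^2, na.rm = TRUE)
  df <- na + nb - 2
  sp2 <- (ss_a + ss_b) / df
  se2 <- sp2 * (1 / na + 1 / nb)
  dm <- mu_a - mu_b
  t <- dm / sqrt(se2)
  zero_se <- !is.na(se2) & se2 == 0
  t[zero_se & dm == 0] <- 0
  t[zero_se & dm != 0] <- sign(dm[zero_se & dm != 0]) * Inf
  t[na < 2 | nb < 2] <- NA_real_
  list(t = t, df = df, mean_a = mu_a, mean_b = mu_b, n_a = na, n_b = nb)
}

row_t_p <- function(stats) {
  p <- 2 * pt(-abs(stats$t), stats$df)
  p[is.infinite(stats$t)] <- 0
  p
}

# All (or a uniform sample of) balanced label assignments: which of the
# pooled sample positions 1..n carry group-A labels. The observed
# assignment (positions 1..n_a) and, for equal group sizes, its complement
# are excluded: both reproduce the observed |t| for every site, and
# including them in the null caps attainable q-values at
# 2 / #assignments * #sites trivially >= the FDR threshold for small
# balanced designs (e.g. q >= 0.1 exactly for 3 vs 3).
balanced_assignments <- function(n, n_a, n_permutations, seed) {
  identity_col <- seq_len(n_a)
  complement_col <- if (2 * n_a == n) seq.int(n_a + 1, n) else NULL
  is_excluded <- function(col) {
    identical(col, identity_col) ||
      (!is.null(complement_col) && identical(col, complement_col))
  }
  n_total <- choose(n, n_a)
  if (n_total <= n_permutations + 1 + !is.null(complement_col)) {
    all_cols <- utils::combn(n, n_a)
    keep <- !apply(all_cols, 2, is_excluded)
    all_cols[, keep, drop = FALSE]
  } else {
    withr::with_seed(seed, {
      cols <- lapply(seq_len(n_permutations), function(i) {
        repeat {
          col <- sort(sample.int(n, n_a))
          if (!is_excluded(col)) return(col)
        }
      })
      matrix(unlist(cols), nrow = n_a)
    })
  }
}

#' Permutation-based false discovery rate
#'
#' Estimates per-site q-values from the permutation null distribution of
#' the absolute t statistic, in the style of proteomics permutation FDR.
#' Observed |t| values are computed under the given A/B labels; the null
#' pool collects |t| recomputed under balanced label permutations —
#' exhaustive over the `choose(n, n_a)` assignments when few enough, else
#' uniformly sampled with the given seed, in both cases excluding the
#' observed assignment and (for equal group sizes) its complement, which
#' reproduce the observed statistics rather than draws from the null and
#' would otherwise cap the attainable q-values of small balanced designs
#' at the FDR threshold itself. For each site,
#' `q = [mean over permutations of #(null |t| >= |t_site|)] /
#'      #(observed |t| >= |t_site|)`,
#' clipped to \[0, 1\] and made monotone non-increasing in |t|. Sites with
#' an undefined observed t are excluded (q is `NA`).
#'
#' @param ox An oxidation (or any site-by-sample) tibble: `site_key` plus
#'   numeric sample columns.
#' @param group_labels Named character vector mapping sample column names
#'   to `"A"` or `"B"`; samples not named are ignored.
#' @param n_permutations Maximum number of permutations (default 1000).
#' @param seed Integer seed for permutation sampling.
#'
#' @return A tibble with columns `site_key`, `t_statistic`, `p_value`,
#'   `q_value`.
#' @export
permutation_fdr <- function(ox, group_labels, n_permutations = 1000,
                            seed = 1L) {
  if (n_permutations < 1) stop_usage("n_permutations must be >= 1")
  samples_a <- names(group_labels)[group_labels == "A"]
  samples_b <- names(group_labels)[group_labels == "B"]
  missing_samples <- setdiff(c(samples_a, samples_b), names(ox))
  if (length(missing_samples) > 0) {
    stop_data("sample(s) in group_labels absent from table: %s",
              paste(missing_samples, collapse = ", "))
  }
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop_usage("each group needs at least 2 samples")
  }
  m <- as.matrix(ox[c(samples_a, samples_b)])
  n_a <- length(samples_a)
  n <- ncol(m)
  obs <- row_t_stats(m, seq_len(n_a), seq.int(n_a + 1, n))
  p <- row_t_p(obs)

  assigns <- balanced_assignments(n, n_a, n_permutations, seed)
  n_perm <- ncol(assigns)
  null_abs_t <- unlist(lapply(seq_len(n_perm), function(k) {
    idx_a <- assigns[, k]
    tt <- row_t_stats(m, idx_a, setdiff(seq_len(n), idx_a))$t
    abs(tt[!is.na(tt)])
  }))

  abs_obs <- abs(obs$t)
  defined <- !is.na(abs_obs)
  q <- rep(NA_real_, length(abs_obs))
  if (any(defined)) {
    ao <- abs_obs[defined]
    # counts of values >= threshold via sorted lookup
    sorted_null <- sort(null_abs_t)
    n_null <- length(sorted_null)
    cnt_null <- n_null - findInterval(ao, sorted_null, left.open = TRUE)
    sorted_obs <- sort(ao)
    cnt_obs <- length(ao) - findInterval(ao, sorted_obs, left.open = TRUE)
    q_raw <- pmin(1, (cnt_null / n_perm) / cnt_obs)
    # monotone non-increasing in |t|
    ord <- order(ao, decreasing = TRUE)
    q_mono <- q_raw
    q_mono[ord] <- cummax(q_raw[ord])
    q[defined] <- q_mono
  }
  tibble(site_key = ox$site_key, t_statistic = obs$t, p_value = p,
         q_value = q)
}

#' Differential oxidation between two conditions
#'
#' The dual-criterion differential call. Per site, the mean oxidation of
#' each condition, their difference `delta = mean_B - mean_A`, the
#' equal-variance t statistic, its p-value and the permutation-FDR q-value
#' are computed. The primary significance criterion is `q < q_max`; if
#' `allow_fallback` and no site satisfies both `q < q_max` and
#' `|delta| > delta_min`, the criterion for the whole comparison falls back
#' to `p < p_fallback`. A site is called `oxidized` when
#' `delta > +delta_min` and the active criterion holds, `reduced` when
#' `delta < -delta_min` and the criterion holds, otherwise `ns`.
#'
#' @param ox An oxidation tibble (`site_key` + sample columns).
#' @param design A validated channel design.
#' @param group_a,group_b Condition names to compare (delta is B - A).
#' @param delta_min Minimum absolute oxidation change, percentage points
#'   (default 5).
#' @param q_max Primary FDR threshold (default 0.1).
#' @param p_fallback Fallback p-value threshold (default 0.05).
#' @param allow_fallback Whether the per-comparison fallback is allowed.
#' @param n_permutations,seed Passed to [permutation_fdr()].
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test (also for the permutation null).
#'
#' @return A tibble of class `diff_redox` with columns `site_key`,
#'   `mean_ox_a`, `mean_ox_b`, `delta`, `t_statistic`, `p_value`,
#'   `q_value`, `call` (factor oxidized/reduced/ns) and attribute
#'   `criterion_used` (`"fdr"` or `"p_fallback"`; see [glance()]).
#' @export
differential_oxidation <- function(ox, design, group_a, group_b,
                                   delta_min = 5, q_max = 0.1,
                                   p_fallback = 0.05, allow_fallback = TRUE,
                                   n_permutations = 1000, seed = 1L,
                                   welch = FALSE) {
  st <- sample_table(validate_channel_design(design))
  for (g in c(group_a, group_b)) {
    if (!g %in% st$condition) stop_usage("unknown condition: %s", g)
  }
  samples_a <- intersect(st$sample_id[st$condition == group_a], names(ox))
  samples_b <- intersect(st$sample_id[st$condition == group_b], names(ox))
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop_data("conditions '%s' and '%s' need >= 2 replicates present in the table",
              group_a, group_b)
  }
  if (welch) {
    # Welch variant kept simple: per-site tests without vectorization
    res <- purrr::map(seq_len(nrow(ox)), function(i) {
      two_sample_t(as.numeric(ox[i, samples_a]), as.numeric(ox[i, samples_b]),
                   welch = TRUE)
    })
    t_stat <- purrr::map_dbl(res, "t")
    p <- purrr::map_dbl(res, "p")
    m <- as.matrix(ox[c(samples_a, samples_b)])
    mu_a <- rowMeans(m[, seq_along(samples_a), drop = FALSE], na.rm = TRUE)
    mu_b <- rowMeans(m[, -seq_along(samples_a), drop = FALSE], na.rm = TRUE)
    labels <- setNames(rep(c("A", "B"), c(length(samples_a), length(samples_b))),
                       c(samples_a, samples_b))
    q <- permutation_fdr(ox, labels, n_permutations, seed)$q_value
  } else {
    labels <- setNames(rep(c("A", "B"), c(length(samples_a), length(samples_b))),
                       c(samples_a, samples_b))
    fdr <- permutation_fdr(ox, labels, n_permutations, seed)
    t_stat <- fdr$t_statistic
    p <- fdr$p_value
    q <- fdr$q_value
    m <- as.matrix(ox[c(samples_a, samples_b)])
    mu_a <- rowMeans(m[, seq_along(samples_a), drop = FALSE], na.rm = TRUE)
    mu_b <- rowMeans(m[, -seq_along(samples_a), drop = FALSE], na.rm = TRUE)
  }
  mu_a[!is.finite(mu_a)] <- NA_real_
  mu_b[!is.finite(mu_b)] <- NA_real_
  delta <- mu_b - mu_a

  cls <- classify_differential(delta, p, q, delta_min, q_max, p_fallback,
                               allow_fallback)

  out <- tibble(
    site_key = ox$site_key,
    mean_ox_a = mu_a, mean_ox_b = mu_b, delta = delta,
    t_statistic = t_stat, p_value = p, q_value = q,
    call = factor(cls$call, levels = c("oxidized", "reduced", "ns"))
  )
  attr(out, "criterion_used") <- cls$criterion_used
  attr(out, "params") <- list(group_a = group_a, group_b = group_b,
                              delta_min = delta_min, q_max = q_max,
                              p_fallback = p_fallback,
                              allow_fallback = allow_fallback,
                              n_permutations = n_permutations, seed = seed)
  class(out) <- c("diff_redox", class(out))
  out
}

#' Apply the dual-criterion differential rule to per-site summaries
#'
#' The decision rule of [differential_oxidation()], factored out so it can
#' be applied to already-computed per-site summaries: primary criterion
#' `q < q_max`; per-comparison fallback to `p < p_fallback` when no site
#' satisfies both the primary criterion and `|delta| > delta_min`; a call
#' additionally requires the oxidation change to exceed `delta_min`
#' percentage points in magnitude, with the call direction given by the
#' sign of `delta`.
#'
#' @param delta Oxidation changes (B - A), percentage points.
#' @param p,q Per-site p- and q-values.
#' @param delta_min,q_max,p_fallback,allow_fallback As in
#'   [differential_oxidation()].
#'
#' @return A list with `call` (character vector: oxidized/reduced/ns) and
#'   `criterion_used`.
#' @export
classify_differential <- function(delta, p, q, delta_min = 5, q_max = 0.1,
                                  p_fallback = 0.05, allow_fallback = TRUE) {
  any_primary <- any(!is.na(q) & q < q_max & abs(delta) > delta_min)
  criterion <- if (any_primary || !allow_fallback) "fdr" else "p_fallback"
  sig <- if (criterion == "fdr") !is.na(q) & q < q_max else !is.na(p) & p < p_fallback
  call <- rep("ns", length(delta))
  call[sig & !is.na(delta) & delta > delta_min] <- "oxidized"
  call[sig & !is.na(delta) & delta < -delta_min] <- "reduced"
  list(call = call, criterion_used = criterion)
}

#' Distribution summary of oxidation values
#'
#' Per-sample five-number-style summary (median, first and third quartile,
#' min, max) of non-missing oxidation percentages, plus counts of sites in
#' stated oxidation intervals. Bins are right-open with the final bin
#' closed, so edges `c(0, 50, 100)` give bins `[0, 50)` and `[50, 100]`.
#'
#' @param ox An oxidation tibble.
#' @param interval_edges Increasing numeric vector of bin edges (percent).
#'
#' @return A list of class `distribution_summary` with tibbles `stats`
#'   (one row per sample) and `counts` (one row per sample x interval).
#' @export
distribution_summary <- function(ox, interval_edges = c(0, 10, 25, 50, 75, 90, 100)) {
  sample_cols <- setdiff(names(ox), "site_key")
  if (is.unsorted(interval_edges, strictly = TRUE)) {
    stop_usage("interval_edges must be strictly increasing")
  }
  stats_tbl <- purrr::map_dfr(sample_cols, function(s) {
    v <- ox[[s]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble(sample_id = s, n = 0L, median = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, min = NA_real_, max = NA_real_))
    }
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(sample_id = s, n = length(v), median = qs[2], q1 = qs[1],
           q3 = qs[3], min = min(v), max = max(v))
  })
  n_bins <- length(interval_edges) - 1
  bin_label <- paste0("[", interval_edges[-length(interval_edges)], ",",
                      interval_edges[-1],
                      c(rep(")", n_bins - 1), "]"))
  counts_tbl <- purrr::map_dfr(sample_cols, function(s) {
    v <- ox[[s]]
    v <- v[!is.na(v) & v >= interval_edges[1] &
             v <= interval_edges[length(interval_edges)]]
    idx <- findInterval(v, interval_edges, rightmost.closed = TRUE)
    tibble(sample_id = s, interval = bin_label,
           count = as.integer(tabulate(idx, nbins = n_bins)))
  })
  structure(list(stats = stats_tbl, counts = counts_tbl,
                 interval_edges = interval_edges),
            class = "distribution_summary")
}

#' One-way ANOVA with Fisher's LSD post-hoc tests
#'
#' One-way analysis of variance across groups of oxidation summaries,
#' followed by unprotected pairwise comparisons using the pooled
#' within-group mean square (Fisher's least significant difference).
#' Groups with fewer than two values are excluded with a warning; with
#' fewer than two usable groups the result is undefined.
#'
#' @param data A data frame with a numeric `value` column and a `group`
#'   column (or supply a named list of numeric vectors).
#'
#' @return A list of class `anova_lsd`: `f_statistic`, `p_value`, `df`,
#'   and `pairwise` (tibble with `group_1`, `group_2`, `mean_diff`,
#'   `t_statistic`, `p_value`).
#' @export
anova_fisher_lsd <- function(data) {
  if (is.data.frame(data)) {
    groups <- split(data$value, data$group)
  } else {
    groups <- data
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  usable <- lengths(groups) >= 2
  if (any(!usable)) {
    warn(sprintf("excluding group(s) with < 2 values: %s",
                 paste(names(groups)[!usable], collapse = ", ")))
    groups <- groups[usable]
  }
  k <- length(groups)
  if (k < 2) {
    return(structure(list(f_statistic = NA_real_, p_value = NA_real_,
                          df = c(NA_real_, NA_real_), pairwise = tibble()),
                     class = "anova_lsd"))
  }
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n_tot - k
  ms_between <- ss_between / df1
  mse <- ss_within / df2
  f <- if (mse == 0) {
    if (ms_between == 0) 0 else Inf
  } else {
    ms_between / mse
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(names(groups), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    dm <- means[[g1]] - means[[g2]]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    t <- if (se == 0) { if (dm == 0) 0 else sign(dm) * Inf } else dm / se
    pp <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df2)
    tibble(group_1 = g1, group_2 = g2, mean_diff = dm, t_statistic = t,
           p_value = pp)
  })
  structure(list(f_statistic = f, p_value = p, df = c(df1, df2),
                 pairwise = pairwise),
            class = "anova_lsd")
}

#' Pearson correlation of shared quantified sites
#'
#' Correlates two oxidation profiles (e.g. condition means from two
#' datasets) over the sites non-missing in both. With fewer than three
#' shared sites the correlation is undefined and `NA` is returned with a
#' warning.
#'
#' @param ox_a,ox_b Data frames with a `site_key` column and one numeric
#'   value column each (the first numeric column is used), or named numeric
#'   vectors keyed by site.
#'
#' @return A one-row tibble with `pearson_r` and `n_shared`.
#' @export
correlate_shared_sites <- function(ox_a, ox_b) {
  as_profile <- function(x) {
    if (is.data.frame(x)) {
      num_cols <- names(x)[vapply(x, is.numeric, logical(1))]
      setNames(x[[num_cols[1]]], x$site_key)
    } else {
      x
    }
  }
  a <- as_profile(ox_a)
  b <- as_profile(ox_b)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 3) {
    warn(sprintf("only %d shared non-missing sites; correlation undefined",
                 length(shared)))
    return(tibble(pearson_r = NA_real_, n_shared = length(shared)))
  }
  tibble(pearson_r = cor(a[shared], b[shared]), n_shared = length(shared))
}
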