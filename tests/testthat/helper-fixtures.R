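# Fixture builders shared across tests. Everything is generated in code;
# files are written to tempdir() on demand.

# Design with n_samples per condition, one SH + one Sox channel per sample.
toy_design <- function(conditions = c("ctrl", "trt"), n_replicates = 3,
                       plex_run = "run1") {
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         condition = conditions,
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste0(samples$condition, "_", samples$replicate)
  tibble::tibble(
    channel_id = as.vector(rbind(paste0(samples$sample_id, ".SH"),
                                 paste0(samples$sample_id, ".Sox"))),
    plex_run = plex_run,
    sample_id = rep(samples$sample_id, each = 2),
    condition = rep(samples$condition, each = 2),
    replicate = rep(samples$replicate, each = 2),
    label_class = rep(c("SH", "Sox"), nrow(samples))
  )
}

# Reporter-export data frame in the default file dialect.
toy_export <- function(accession, sequence, positions, contaminant,
                       intensities) {
  df <- tibble::tibble(
    Accession = accession,
    Sequence = sequence,
    `Positions in Proteins` = positions,
    Contaminant = contaminant
  )
  dplyr::bind_cols(df, tibble::as_tibble(intensities))
}

write_tsv_tmp <- function(df, name = "fixture.tsv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_tsv(df, path, na = "NA")
  path
}

# Oxidation tibble from a plain matrix (rows = sites, cols = samples).
ox_from_matrix <- function(m, sample_ids = colnames(m)) {
  out <- tibble::tibble(site_key = sprintf("P%04d:Cys%d", seq_len(nrow(m)),
                                           seq_len(nrow(m)) %% 100 + 1L))
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- m[, j]
  out
}

# Independent brute-force permutation-FDR oracle: scalar loops, explicit
# enumeration via combn, the same null-exclusion and tie conventions
# derived from first principles rather than shared code.
brute_force_perm_fdr <- function(ox, samples_a, samples_b) {
  m <- as.matrix(ox[c(samples_a, samples_b)])
  n_a <- length(samples_a)
  n <- ncol(m)
  scalar_t <- function(row, idx_a) {
    a <- row[idx_a]; b <- row[-idx_a]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    se2 <- sp2 * (1 / length(a) + 1 / length(b))
    d <- mean(a) - mean(b)
    if (se2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / sqrt(se2)
  }
  obs <- apply(m, 1, scalar_t, idx_a = seq_len(n_a))
  all_assign <- utils::combn(n, n_a)
  keep <- logical(ncol(all_assign))
  for (k in seq_len(ncol(all_assign))) {
    col <- all_assign[, k]
    is_id <- identical(col, seq_len(n_a))
    is_comp <- (2 * n_a == n) && identical(col, seq.int(n_a + 1, n))
    keep[k] <- !is_id && !is_comp
  }
  all_assign <- all_assign[, keep, drop = FALSE]
  null_abs <- c()
  for (k in seq_len(ncol(all_assign))) {
    tk <- apply(m, 1, scalar_t, idx_a = all_assign[, k])
    null_abs <- c(null_abs, abs(tk[!is.na(tk)]))
  }
  abs_obs <- abs(obs)
  q <- rep(NA_real_, length(obs))
  for (i in seq_along(obs)) {
    if (is.na(abs_obs[i])) next
    cnt_null <- sum(null_abs >= abs_obs[i])
    cnt_obs <- sum(abs_obs >= abs_obs[i], na.rm = TRUE)
    q[i] <- min(1, (cnt_null / ncol(all_assign)) / cnt_obs)
  }
  ord <- order(abs_obs, decreasing = TRUE, na.last = NA)
  running <- -Inf
  for (i in ord) {
    running <- max(running, q[i])
    q[i] <- running
  }
  q
}

# Mean absolute error of replicate-mean estimated oxidation vs planted
# truth, per peptide x condition.
oxidation_mae <- function(ox, design, truth) {
  est <- tidyr::pivot_longer(ox, -"site_key", names_to = "sample_id",
                             values_to = "ox_pct") |>
    dplyr::left_join(dplyr::distinct(design, .data$sample_id, .data$condition),
                     by = "sample_id") |>
    dplyr::group_by(.data$site_key, .data$condition) |>
    dplyr::summarise(est = mean(.data$ox_pct, na.rm = TRUE), .groups = "drop") |>
    dplyr::inner_join(truth, by = c("site_key", "condition"))
  mean(abs(est$est - est$true_oxidation_pct), na.rm = TRUE)
}
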