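#' Configuration for a synthetic redox experiment
#'
#' Assembles and validates the parameters of the synthetic iodoTMT
#' generator. Defaults emulate the statistical structure of a typical
#' sequential-labelling experiment: thousands of Cys peptides, two
#' conditions with three biological replicates each, one SH and one Sox
#' channel per sample in a single plex run, multiplicative log-normal
#' replicate noise at a coefficient of variation near 10 %, per-channel
#' multiplicative biases, zero-encoded missing values, and a small fraction
#' of peptides carrying a planted between-condition oxidation shift.
#'
#' The default true-oxidation distribution is a mixture of Beta(1.2, 10)
#' (a mostly reduced proteome) with a 5 % Beta(5, 1.5) high-oxidation tail,
#' giving the right-skewed site-oxidation distribution seen in cellular
#' redox proteomes; supply `true_oxidation` to override.
#'
#' @param n_peptides Number of Cys peptides.
#' @param conditions Character vector of condition names. The planted shift
#'   is applied to the last condition.
#' @param n_replicates Biological replicates per condition.
#' @param true_oxidation Optional numeric vector (length `n_peptides`) of
#'   baseline oxidation fractions in \[0, 1\]; drawn from the default
#'   mixture when `NULL`.
#' @param differential_fraction Fraction of peptides with a planted shift.
#' @param shift_size Planted shift in oxidation percentage points (signed;
#'   applied to the last condition and clipped to \[0, 100\]).
#' @param base_intensity_log2_mean,base_intensity_log2_sd Location and
#'   spread of per-peptide total abundance on log2 scale.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal channel noise (>= 0; 0 gives the noise-free limit).
#' @param channel_bias_log2_sd Spread of per-channel multiplicative biases
#'   on log2 scale. Biases are mean-centered within each label class: the
#'   class-mean component is not identifiable from reporter data (it is
#'   equivalent to a global rescaling of SH or Sox label recovery), so only
#'   the identifiable within-class component is planted.
#' @param missing_rate Probability that any intensity cell is zeroed
#'   (missing), in \[0, 1).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   config.
#'
#' @return A validated config object (list, class `synthetic_redox_config`).
#' @export
synthetic_redox_config <- function(n_peptides = 2000,
                                   conditions = c("untreated", "AZA"),
                                   n_replicates = 3,
                                   true_oxidation = NULL,
                                   differential_fraction = 0.05,
                                   shift_size = 15,
                                   base_intensity_log2_mean = 20,
                                   base_intensity_log2_sd = 2,
                                   replicate_cv = 0.10,
                                   channel_bias_log2_sd = 0.3,
                                   missing_rate = 0.05,
                                   seed = 1L) {
  cfg <- list(
    n_peptides = as.integer(n_peptides),
    conditions = as.character(conditions),
    n_replicates = as.integer(n_replicates),
    true_oxidation = true_oxidation,
    differential_fraction = differential_fraction,
    shift_size = shift_size,
    base_intensity_log2_mean = base_intensity_log2_mean,
    base_intensity_log2_sd = base_intensity_log2_sd,
    replicate_cv = replicate_cv,
    channel_bias_log2_sd = channel_bias_log2_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_peptides < 1) stop_usage("n_peptides must be positive")
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions)) {
    stop_usage("conditions must be a non-empty set of distinct names")
  }
  if (cfg$n_replicates < 1) stop_usage("n_replicates must be positive")
  if (cfg$differential_fraction < 0 || cfg$differential_fraction >= 1) {
    stop_usage("differential_fraction must be in [0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_usage("missing_rate must be in [0, 1)")
  }
  if (cfg$replicate_cv < 0) stop_usage("replicate_cv must be >= 0")
  if (cfg$channel_bias_log2_sd < 0) stop_usage("channel_bias_log2_sd must be >= 0")
  if (!is.null(true_oxidation)) {
    if (length(true_oxidation) != cfg$n_peptides ||
        any(true_oxidation < 0 | true_oxidation > 1)) {
      stop_usage("true_oxidation must have length n_peptides with values in [0, 1]")
    }
  }
  structure(cfg, class = "synthetic_redox_config")
}

# log-normal multiplicative noise with mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a sequential iodoTMT redox experiment
#'
#' Generates a Cys-peptide reporter-intensity table with known ground truth.
#' For peptide i in sample s of condition c, total abundance is
#' `A = 2^N(base_mean, base_sd)`; the Sox channel measures `A * ox * e1` and
#' the SH channel `A * (1 - ox) * e2` with `e1, e2` independent log-normal
#' multipliers of mean 1 and CV `replicate_cv`. Each channel's intensities
#' are then multiplied by that channel's bias `2^b` (log2 biases drawn
#' `N(0, channel_bias_log2_sd)` and mean-centered within each label class;
#' see [synthetic_redox_config()]), and each cell is independently zeroed
#' with probability `missing_rate` (zero encodes "not observed").
#'
#' The random draws are consumed in a fixed order independent of the
#' parameter values, so two configs differing only in, say,
#' `channel_bias_log2_sd` share all other random components — this supports
#' paired bias-cancellation experiments.
#'
#' @param config A [synthetic_redox_config()].
#'
#' @return A list of class `synthetic_redox_experiment` with elements
#'   `reporter` (tibble shaped like [read_reporter_table()] output),
#'   `design` (validated channel design), and `truth` (list with
#'   `oxidation`: tibble of site_key, condition, true oxidation %, planted
#'   shift indicator and signed shift; `channel_bias`: tibble of per-channel
#'   log2 biases; `config`).
#' @export
simulate_redox_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_redox_config"))
  n <- config$n_peptides
  conds <- config$conditions
  n_cond <- length(conds)
  n_rep <- config$n_replicates

  samples <- tibble(
    sample_id = paste0(rep(conds, each = n_rep), "_", rep(seq_len(n_rep), n_cond)),
    condition = rep(conds, each = n_rep),
    replicate = rep(seq_len(n_rep), n_cond)
  )
  design <- tibble(
    channel_id = as.vector(rbind(paste0(samples$sample_id, ".SH"),
                                 paste0(samples$sample_id, ".Sox"))),
    plex_run = "run1",
    sample_id = rep(samples$sample_id, each = 2),
    condition = rep(samples$condition, each = 2),
    replicate = rep(samples$replicate, each = 2),
    label_class = rep(c("SH", "Sox"), nrow(samples))
  )
  design <- validate_channel_design(design)
  n_samp <- nrow(samples)
  n_chan <- nrow(design)

  withr::with_seed(config$seed, {
    # 1. baseline oxidation fractions (draws consumed even when overridden,
    #    to keep the RNG stream alignment independent of the override)
    tail_flag <- rbinom(n, 1, 0.05) == 1
    body_draw <- rbeta(n, 1.2, 10)
    tail_draw <- rbeta(n, 5, 1.5)
    ox_base <- ifelse(tail_flag, tail_draw, body_draw)
    if (!is.null(config$true_oxidation)) ox_base <- config$true_oxidation

    # 2. planted differential peptides: shift applied to the last condition
    n_diff <- round(config$differential_fraction * n)
    diff_idx <- if (n_diff > 0) sample.int(n, n_diff) else integer(0)
    ox_true <- matrix(ox_base, nrow = n, ncol = n_cond)
    colnames(ox_true) <- conds
    shift_frac <- config$shift_size / 100
    if (n_diff > 0) {
      shifted <- pmin(1, pmax(0, ox_base[diff_idx] + shift_frac))
      if (all(shifted == ox_base[diff_idx]) && shift_frac != 0) {
        stop_usage("infeasible config: the planted shift is clipped away for every selected peptide")
      }
      ox_true[diff_idx, n_cond] <- shifted
    }

    # 3. per-peptide per-sample total abundance
    A <- matrix(2^rnorm(n * n_samp, config$base_intensity_log2_mean,
                        config$base_intensity_log2_sd), n, n_samp)
    # 4. multiplicative replicate noise, one draw per channel cell
    eps_sox <- matrix(rlnorm_cv(n * n_samp, config$replicate_cv), n, n_samp)
    eps_sh <- matrix(rlnorm_cv(n * n_samp, config$replicate_cv), n, n_samp)
    # 5. channel biases, mean-centered within label class
    z <- rnorm(n_chan)
    z <- z - ave(z, design$label_class)
    bias_log2 <- config$channel_bias_log2_sd * z
    # 6. missingness mask
    miss <- matrix(runif(n * n_chan) < config$missing_rate, n, n_chan)
  })

  ox_samp <- ox_true[, match(samples$condition, conds), drop = FALSE]
  intens <- matrix(0, n, n_chan)
  colnames(intens) <- design$channel_id
  for (j in seq_len(n_samp)) {
    ch <- design$channel_id[design$sample_id == samples$sample_id[j]]
    ch_sh <- ch[design$label_class[match(ch, design$channel_id)] == "SH"]
    ch_sox <- setdiff(ch, ch_sh)
    b_sh <- 2^bias_log2[match(ch_sh, design$channel_id)]
    b_sox <- 2^bias_log2[match(ch_sox, design$channel_id)]
    intens[, ch_sh] <- A[, j] * (1 - ox_samp[, j]) * eps_sh[, j] * b_sh
    intens[, ch_sox] <- A[, j] * ox_samp[, j] * eps_sox[, j] * b_sox
  }
  intens[miss] <- 0

  acc <- sprintf("SYN%05d", seq_len(n))
  pos <- seq_len(n) %% 400 + 1L
  site_key <- make_site_key(acc, as.list(pos))

  reporter <- dplyr::bind_cols(
    tibble(site_key = site_key, accession = acc,
           positions = as.character(pos), all_accessions = acc),
    as_tibble(intens)
  ) |>
    dplyr::arrange(.data$site_key)

  truth_ox <- tibble(
    site_key = rep(site_key, n_cond),
    condition = rep(conds, each = n),
    true_oxidation_pct = 100 * as.vector(ox_true),
    is_differential = rep(seq_len(n) %in% diff_idx, n_cond),
    planted_shift_pct = ifelse(
      rep(seq_len(n) %in% diff_idx, n_cond) &
        rep(conds, each = n) == conds[n_cond],
      100 * (ox_true[, n_cond] - ox_base), 0)
  ) |>
    dplyr::arrange(.data$site_key, .data$condition)

  structure(
    list(
      reporter = reporter,
      design = design,
      truth = list(
        oxidation = truth_ox,
        channel_bias = tibble(channel_id = design$channel_id,
                              bias_log2 = bias_log2),
        config = config
      )
    ),
    class = "synthetic_redox_experiment"
  )
}

#' Configuration for a synthetic protein-abundance experiment
#'
#' Parameters of the synthetic TMT 16-plex quantitative-proteomics
#' generator: two conditions with eight channels each, log-normal protein
#' abundances, planted log2 fold-changes on a stated fraction of proteins,
#' additive per-channel log2 biases and zero-encoded missing values.
#'
#' @param n_proteins Number of proteins.
#' @param conditions Two condition names; the fold-change is applied to the
#'   second.
#' @param n_channels_per_condition Channels (replicates) per condition
#'   (default 8, a 16-plex split two ways).
#' @param differential_fraction Fraction of proteins with a planted
#'   fold-change.
#' @param log2_fc Absolute planted log2 fold-change (sign randomized per
#'   protein).
#' @param base_log2_mean,base_log2_sd Protein abundance location/spread on
#'   log2 scale.
#' @param noise_log2_sd Per-cell additive noise on log2 scale.
#' @param channel_bias_log2_sd Per-channel additive log2 bias spread.
#' @param missing_rate Probability a cell is zeroed.
#' @param seed Integer seed.
#'
#' @return A config object (class `synthetic_abundance_config`).
#' @export
synthetic_abundance_config <- function(n_proteins = 3000,
                                       conditions = c("SAZA", "RAZA"),
                                       n_channels_per_condition = 8,
                                       differential_fraction = 0.05,
                                       log2_fc = 1,
                                       base_log2_mean = 22,
                                       base_log2_sd = 2,
                                       noise_log2_sd = 0.25,
                                       channel_bias_log2_sd = 0.3,
                                       missing_rate = 0.02,
                                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    conditions = as.character(conditions),
    n_channels_per_condition = as.integer(n_channels_per_condition),
    differential_fraction = differential_fraction,
    log2_fc = log2_fc,
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    noise_log2_sd = noise_log2_sd,
    channel_bias_log2_sd = channel_bias_log2_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1) stop_usage("n_proteins must be positive")
  if (length(cfg$conditions) != 2) stop_usage("exactly two conditions required")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_usage("missing_rate must be in [0, 1)")
  }
  if (cfg$differential_fraction < 0 || cfg$differential_fraction >= 1) {
    stop_usage("differential_fraction must be in [0, 1)")
  }
  structure(cfg, class = "synthetic_abundance_config")
}

#' Simulate a TMT protein-abundance experiment
#'
#' Generates a protein-by-channel intensity table (linear scale, zeros as
#' missing) with known planted log2 fold-changes, plus the channel design
#' (columns `channel_id`, `condition`, `replicate`) and the truth table.
#'
#' @param config A [synthetic_abundance_config()].
#'
#' @return A list of class `synthetic_abundance_experiment` with elements
#'   `abundance` (tibble: `accession` + one intensity column per channel),
#'   `design`, and `truth` (tibble: `accession`, `true_log2_fc`,
#'   `is_differential`).
#' @export
simulate_abundance_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_abundance_config"))
  n <- config$n_proteins
  k <- config$n_channels_per_condition
  conds <- config$conditions
  design <- tibble(
    channel_id = paste0("tmt", sprintf("%02d", seq_len(2 * k))),
    condition = rep(conds, each = k),
    replicate = rep(seq_len(k), 2)
  )
  n_chan <- nrow(design)

  withr::with_seed(config$seed, {
    base <- rnorm(n, config$base_log2_mean, config$base_log2_sd)
    n_diff <- round(config$differential_fraction * n)
    diff_idx <- if (n_diff > 0) sample.int(n, n_diff) else integer(0)
    signs <- sample(c(-1, 1), n, replace = TRUE)
    fc <- numeric(n)
    fc[diff_idx] <- config$log2_fc * signs[diff_idx]
    noise <- matrix(rnorm(n * n_chan, 0, config$noise_log2_sd), n, n_chan)
    bias <- rnorm(n_chan, 0, config$channel_bias_log2_sd)
    miss <- matrix(runif(n * n_chan) < config$missing_rate, n, n_chan)
  })

  group2 <- design$condition == conds[2]
  log2_val <- base + outer(fc, as.numeric(group2)) + noise +
    matrix(bias, n, n_chan, byrow = TRUE)
  intens <- 2^log2_val
  intens[miss] <- 0
  colnames(intens) <- design$channel_id

  acc <- sprintf("PROT%05d", seq_len(n))
  abundance <- dplyr::bind_cols(tibble(accession = acc), as_tibble(intens))
  truth <- tibble(accession = acc, true_log2_fc = fc,
                  is_differential = seq_len(n) %in% diff_idx)
  structure(
    list(abundance = abundance, design = design, truth = truth,
         config = config),
    class = "synthetic_abundance_experiment"
  )
}
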