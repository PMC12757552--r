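test_that("pooled t-test matches the textbook computation and t.test", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  # antisymmetry
  swap <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  # zero-variance convention and undefined cases
  expect_equal(two_sample_t(c(5, 5, 5), c(5, 5, 5)), list(t = 0, p = 1, df = 4))
  zv <- two_sample_t(c(5, 5), c(7, 7))
  expect_equal(zv$t, -Inf)
  expect_equal(zv$p, 0)
  expect_true(is.na(two_sample_t(c(1), c(2, 3, 4))$t))

  # random cases against the stats::t.test oracle
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -2, 2))
    ours <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    refw <- t.test(a, b)
    oursw <- two_sample_t(a, b, welch = TRUE)
    expect_equal(oursw$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(oursw$p, refw$p.value, tolerance = 1e-12)
  }
})

test_that("exhaustive permutation FDR equals the brute-force enumeration", {
  labels <- setNames(rep(c("A", "B"), each = 3),
                     c("a1", "a2", "a3", "b1", "b2", "b3"))
  for (s in 1:3) {
    set.seed(100 + s)
    n_sites <- 40
    m <- matrix(rnorm(n_sites * 6, 50, 8), n_sites, 6)
    m[sample(length(m), 10)] <- NA            # ragged valid counts
    m[1:4, 4:6] <- m[1:4, 4:6] + 25           # a few strong shifts
    ox <- ox_from_matrix(m, sample_ids = names(labels))
    got <- permutation_fdr(ox, labels, n_permutations = 1000, seed = s)
    want <- brute_force_perm_fdr(ox, c("a1", "a2", "a3"),
                                 c("b1", "b2", "b3"))
    expect_equal(got$q_value, want, tolerance = 1e-12)
  }
})

test_that("a site dominating every null statistic gets q = 0", {
  labels <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  set.seed(1)
  m <- matrix(rnorm(30 * 6, 50, 5), 30, 6)
  m[1, ] <- c(10, 10.01, 9.99, 90, 90.01, 89.99)  # overwhelming shift
  ox <- ox_from_matrix(m, sample_ids = paste0("s", 1:6))
  got <- permutation_fdr(ox, labels, seed = 2)
  expect_equal(got$q_value[1], 0)
  expect_error(permutation_fdr(ox, labels, n_permutations = 0),
               class = "redoxtmt_usage_error")
})

test_that("permutation q-values are monotone in |t| and within [0, 1]", {
  labels <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  set.seed(3)
  m <- matrix(rnorm(200 * 8, 40, 6), 200, 8)
  ox <- ox_from_matrix(m, sample_ids = paste0("s", 1:8))
  got <- permutation_fdr(ox, labels, n_permutations = 200, seed = 4)
  expect_true(all(got$q_value >= 0 & got$q_value <= 1, na.rm = TRUE))
  ord <- order(abs(got$t_statistic), decreasing = TRUE)
  q_sorted <- got$q_value[ord]
  expect_true(all(diff(q_sorted[!is.na(q_sorted)]) >= 0))
})

test_that("the dual-criterion differential rule reproduces worked scenarios", {
  # a 5 % -> 26 % oxidation increase with q = 0.03 is called oxidized
  one <- classify_differential(delta = 21, p = 0.001, q = 0.03)
  expect_equal(one$call, "oxidized")
  expect_equal(one$criterion_used, "fdr")
  # highly significant but below the 5-point change threshold
  expect_equal(classify_differential(delta = 4.9, p = 1e-4, q = 0.001)$call,
               "ns")
  # non-significant q with the fallback disabled
  expect_equal(classify_differential(delta = 12, p = 0.2, q = 0.4,
                                     allow_fallback = FALSE)$call, "ns")
  # the fallback triggers per comparison when nothing passes the FDR rule
  fb <- classify_differential(delta = c(12, -8, 2), p = c(0.01, 0.2, 0.001),
                              q = c(0.4, 0.5, 0.2))
  expect_equal(fb$criterion_used, "p_fallback")
  expect_equal(fb$call, c("oxidized", "ns", "ns"))
  # one FDR-passing site keeps the whole comparison on the primary rule
  mixed <- classify_differential(delta = c(12, 9), p = c(0.001, 0.01),
                                 q = c(0.05, 0.3))
  expect_equal(mixed$criterion_used, "fdr")
  expect_equal(mixed$call, c("oxidized", "ns"))
})

test_that("differential oxidation calls are antisymmetric in group order", {
  sim <- simulate_redox_experiment(
    synthetic_redox_config(n_peptides = 300, seed = 31))
  ox <- compute_oxidation(normalize_channels(sim$reporter, sim$design),
                          sim$design)
  ab <- differential_oxidation(ox, sim$design, "untreated", "AZA", seed = 5)
  ba <- differential_oxidation(ox, sim$design, "AZA", "untreated", seed = 5)
  expect_equal(ba$delta, -ab$delta)
  expect_equal(abs(ba$t_statistic), abs(ab$t_statistic))
  expect_equal(ba$p_value, ab$p_value)
  expect_equal(ba$q_value, ab$q_value)
  flipped <- c(oxidized = "reduced", reduced = "oxidized", ns = "ns")
  expect_equal(as.character(ba$call),
               unname(flipped[as.character(ab$call)]))
  expect_error(differential_oxidation(ox, sim$design, "untreated", "nope"),
               class = "redoxtmt_usage_error")
})

test_that("an end-to-end planted oxidation shift is recovered as a call", {
  # GLO1-style scenario: ~5 % baseline shifted to ~26 % in the treated arm
  cfg <- synthetic_redox_config(
    n_peptides = 60, replicate_cv = 0.05, channel_bias_log2_sd = 0.1,
    missing_rate = 0, differential_fraction = 0, seed = 17,
    true_oxidation = rep(0.05, 60))
  sim <- simulate_redox_experiment(cfg)
  # plant the shift directly in one peptide's Sox/SH split in both runs
  target <- sim$reporter$site_key[1]
  for (s in unique(sim$design$sample_id[sim$design$condition == "AZA"])) {
    ch_sh <- sim$design$channel_id[sim$design$sample_id == s &
                                     sim$design$label_class == "SH"]
    ch_sox <- sim$design$channel_id[sim$design$sample_id == s &
                                      sim$design$label_class == "Sox"]
    i <- which(sim$reporter$site_key == target)
    tot <- sim$reporter[[ch_sh]][i] + sim$reporter[[ch_sox]][i]
    sim$reporter[[ch_sox]][i] <- 0.26 * tot
    sim$reporter[[ch_sh]][i] <- 0.74 * tot
  }
  ox <- compute_oxidation(normalize_channels(sim$reporter, sim$design),
                          sim$design)
  res <- differential_oxidation(ox, sim$design, "untreated", "AZA", seed = 3)
  rec <- res[res$site_key == target, ]
  expect_equal(as.character(rec$call), "oxidized")
  expect_gt(rec$delta, 15)
})

test_that("distribution summaries follow the stated bin convention", {
  ox <- ox_from_matrix(matrix(c(0, 50, 100), 3, 1), sample_ids = "s1")
  ds <- distribution_summary(ox, interval_edges = c(0, 50, 100))
  expect_equal(ds$counts$count, c(1L, 2L))  # [0,50) and [50,100]
  expect_equal(ds$counts$interval, c("[0,50)", "[50,100]"))

  flat <- ox_from_matrix(matrix(7, 5, 1), sample_ids = "s1")
  st <- tidy(distribution_summary(flat))
  expect_equal(st$q1, st$median)
  expect_equal(st$q3, st$median)

  high <- ox_from_matrix(matrix(c(95, 91, 99.2, 10, 50), 5, 1),
                         sample_ids = "s1")
  ds_high <- distribution_summary(high, interval_edges = c(0, 90, 100))
  expect_equal(ds_high$counts$count[2], 3L)
  expect_error(distribution_summary(high, interval_edges = c(10, 10)),
               class = "redoxtmt_usage_error")
})

test_that("ANOVA with Fisher's LSD matches aov and hand-pooled comparisons", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  res <- anova_fisher_lsd(groups)
  # oracle: stats::aov on the same data
  df <- data.frame(value = unlist(groups),
                   group = rep(names(groups), lengths(groups)))
  ref <- anova(stats::aov(value ~ group, df))
  expect_equal(res$f_statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # LSD pairwise: se = sqrt(MSE * (1/3 + 1/3)) with MSE = 1, df = 6
  p12 <- res$pairwise[res$pairwise$group_1 == "g1" &
                        res$pairwise$group_2 == "g2", ]
  expect_equal(p12$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(p12$p_value, 2 * pt(-3 / sqrt(2 / 3), 6), tolerance = 1e-12)

  # data frame interface agrees with the list interface
  expect_equal(anova_fisher_lsd(df)$f_statistic, res$f_statistic)

  # three identical groups: F = 0, p = 1
  same <- anova_fisher_lsd(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                c = c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  # undersized groups are excluded with a warning
  expect_warning(
    small <- anova_fisher_lsd(list(a = c(1, 2), b = c(3, 4), c = 5)),
    "c")
  expect_equal(nrow(small$pairwise), 1)
  expect_warning(none <- anova_fisher_lsd(list(a = 1, b = c(1, 2))))
  expect_true(is.na(none$f_statistic))
})

test_that("shared-site correlation uses the non-missing intersection", {
  a <- tibble::tibble(site_key = paste0("s", 1:4), ox = c(1, 2, 3, 4))
  b <- tibble::tibble(site_key = paste0("s", 1:4), ox = c(2, 4, 5, 9))
  got <- correlate_shared_sites(a, b)
  expect_equal(got$pearson_r, 0.964764, tolerance = 1e-6)
  expect_equal(got$n_shared, 4)

  expect_equal(correlate_shared_sites(a, a)$pearson_r, 1.0)
  neg <- a
  neg$ox <- 2 * mean(a$ox) - a$ox
  expect_equal(correlate_shared_sites(a, neg)$pearson_r, -1.0)

  b_missing <- b
  b_missing$ox[c(1, 2)] <- NA
  expect_warning(und <- correlate_shared_sites(a, b_missing))
  expect_true(is.na(und$pearson_r))
  expect_equal(und$n_shared, 2)
})
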