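test_that("channel medians are adjusted to the label-class mean of medians", {
  # two SH channels with constant log2 values 10 and 12 -> both become 2^11
  design <- toy_design(conditions = "c", n_replicates = 2)
  rep_tbl <- tibble::tibble(
    site_key = sprintf("P%d:Cys1", 1:5),
    c_1.SH = rep(2^10, 5), c_2.SH = rep(2^12, 5),
    c_1.Sox = rep(2^3, 5), c_2.Sox = rep(2^3, 5)
  )
  norm <- normalize_channels(rep_tbl, design)
  expect_equal(norm$c_1.SH, rep(2^11, 5))
  expect_equal(norm$c_2.SH, rep(2^11, 5))
  # a single channel per label class is a fixed point
  d1 <- toy_design(conditions = "c", n_replicates = 1)
  one <- tibble::tibble(site_key = rep_tbl$site_key,
                        c_1.SH = c(1, 5, 9, 2, 4), c_1.Sox = c(2, 2, 2, 8, 1))
  expect_equal(normalize_channels(one, d1), one)
})

test_that("normalization pins every channel median to its class target", {
  sim <- simulate_redox_experiment(
    synthetic_redox_config(n_peptides = 400, seed = 3))
  norm <- normalize_channels(sim$reporter, sim$design)
  for (cls in c("SH", "Sox")) {
    ch <- sim$design$channel_id[sim$design$label_class == cls]
    pre_meds <- vapply(ch, function(c) {
      v <- sim$reporter[[c]]; median(log2(v[v > 0]))
    }, numeric(1))
    post_meds <- vapply(ch, function(c) {
      v <- norm[[c]]; median(log2(v[v > 0]))
    }, numeric(1))
    expect_equal(unname(post_meds), rep(mean(pre_meds), length(ch)),
                 tolerance = 1e-12)
  }
  # zeros stay zero
  expect_identical(as.matrix(norm[sim$design$channel_id]) == 0,
                   as.matrix(sim$reporter[sim$design$channel_id]) == 0)
})

test_that("class-mean-preserving channel biases cancel exactly", {
  sim <- simulate_redox_experiment(
    synthetic_redox_config(n_peptides = 300, channel_bias_log2_sd = 0,
                           missing_rate = 0, seed = 7))
  ox_ref <- compute_oxidation(normalize_channels(sim$reporter, sim$design),
                              sim$design)
  # inject biases summing to zero (log2) within each label class
  biased <- sim$reporter
  for (cls in c("SH", "Sox")) {
    ch <- sim$design$channel_id[sim$design$label_class == cls]
    b <- seq(-1, 1, length.out = length(ch))
    b <- b - mean(b)
    for (i in seq_along(ch)) biased[[ch[i]]] <- biased[[ch[i]]] * 2^b[i]
  }
  ox_biased <- compute_oxidation(normalize_channels(biased, sim$design),
                                 sim$design)
  expect_equal(as.matrix(ox_biased[-1]), as.matrix(ox_ref[-1]),
               tolerance = 1e-9)
})

test_that("a global intensity rescale leaves oxidation unchanged", {
  sim <- simulate_redox_experiment(
    synthetic_redox_config(n_peptides = 200, seed = 12))
  ox_ref <- compute_oxidation(normalize_channels(sim$reporter, sim$design),
                              sim$design)
  scaled <- sim$reporter
  for (ch in sim$design$channel_id) scaled[[ch]] <- scaled[[ch]] * 3.7
  ox_scaled <- compute_oxidation(normalize_channels(scaled, sim$design),
                                 sim$design)
  expect_equal(as.matrix(ox_scaled[-1]), as.matrix(ox_ref[-1]),
               tolerance = 1e-9)
})

test_that("an all-zero channel is a normalization error naming the channel", {
  design <- toy_design(conditions = "c", n_replicates = 2)
  tbl <- tibble::tibble(site_key = "P1:Cys1", c_1.SH = 0, c_2.SH = 4,
                        c_1.Sox = 2, c_2.Sox = 2)
  expect_error(normalize_channels(tbl, design), "c_1.SH", fixed = TRUE,
               class = "redoxtmt_data_error")
})

test_that("oxidation formula handles boundaries, missing pairs and modes", {
  design <- toy_design(conditions = "c", n_replicates = 1)
  tbl <- tibble::tibble(
    site_key = c("P1:Cys1", "P2:Cys2", "P3:Cys3", "P4:Cys4"),
    c_1.SH = c(50, 0, 74, 0), c_1.Sox = c(0, 0, 26, 33)
  )
  # boundary-value mode: a single zero gives 0 % or 100 %
  ox <- compute_oxidation(tbl, design, strict_pair_na = FALSE)
  expect_equal(ox$c_1, c(0, NA, 26, 100))
  # strict mode (default): any zero channel is missing
  ox_strict <- compute_oxidation(tbl, design)
  expect_equal(ox_strict$c_1, c(NA, NA, 26, NA))

  bad_design <- toy_design(conditions = c("c", "d"), n_replicates = 1)
  expect_error(compute_oxidation(tbl, bad_design),
               class = "redoxtmt_data_error")
})

test_that("oxidation values always lie in [0, 100] or are missing", {
  for (s in 1:3) {
    sim <- simulate_redox_experiment(
      synthetic_redox_config(n_peptides = 300, missing_rate = 0.15, seed = s))
    for (strict in c(TRUE, FALSE)) {
      ox <- compute_oxidation(normalize_channels(sim$reporter, sim$design),
                              sim$design, strict_pair_na = strict)
      v <- as.matrix(ox[-1])
      expect_true(all(is.na(v) | (v >= 0 & v <= 100)))
    }
  }
})

test_that("min-valid filtering respects scope and thresholds", {
  design <- toy_design(conditions = "c", n_replicates = 3)
  ox <- ox_from_matrix(matrix(c(12, NA, NA,
                                5, 6, NA), 2, 3, byrow = TRUE),
                       sample_ids = c("c_1", "c_2", "c_3"))
  expect_equal(nrow(suppressMessages(
    filter_min_valid(ox, 1, "per_condition", design))), 2)
  expect_equal(suppressMessages(
    filter_min_valid(ox, 2, "per_condition", design))$site_key,
    ox$site_key[2])
  expect_equal(suppressMessages(filter_min_valid(ox, 0, "overall")), ox)
  expect_error(filter_min_valid(ox, 4, "overall"),
               class = "redoxtmt_usage_error")
})

test_that("replicate CV matches hand computation and is NA when undefined", {
  design <- toy_design(conditions = "c", n_replicates = 3)
  ox <- ox_from_matrix(matrix(c(10, 10, 10,
                                8, 10, 12,
                                33, NA, NA), 3, 3, byrow = TRUE),
                       sample_ids = c("c_1", "c_2", "c_3"))
  cv <- replicate_cv(ox, design)
  expect_equal(cv$cv_pct[cv$site_key == ox$site_key[1]], 0)
  expect_equal(cv$cv_pct[cv$site_key == ox$site_key[2]], 20)  # sd 2, mean 10
  expect_true(is.na(cv$cv_pct[cv$site_key == ox$site_key[3]]))
  expect_equal(glance(cv)$median_cv_pct, 10)  # median of (0, 20)
})
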