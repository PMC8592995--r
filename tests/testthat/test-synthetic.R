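test_that("simulation_config validates its fields by name", {
  bad_freq <- setNames(c(0.5, 0.6), c("uuu", "ddd"))
  expect_error(simulation_config(pattern_frequencies = bad_freq),
               "pattern_frequencies")
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(effect_log10 = -1), "effect_log10")
  expect_error(simulation_config(missing_rate_per_condition = c(0, 0, 0, 2)),
               "missing_rate_per_condition")
  expect_error(simulation_config(missing_rate_per_condition = c(0, 0)),
               "one rate per dose")
})

test_that("every generator is bit-identical under a repeated seed", {
  cfg <- simulation_config(n_proteins = 120, seed = 99)
  s1 <- simulate_dose_response(cfg)
  s2 <- simulate_dose_response(cfg)
  expect_identical(unclass(s1$quant), unclass(s2$quant))
  expect_identical(s1$truth_patterns, s2$truth_patterns)

  g1 <- simulate_gene_sets(20, c(5, 20), 2, 5, s1$truth_patterns, seed = 7)
  g2 <- simulate_gene_sets(20, c(5, 20), 2, 5, s1$truth_patterns, seed = 7)
  expect_identical(g1$gene_sets, g2$gene_sets)
  expect_identical(g1$enriched_terms, g2$enriched_terms)

  c1 <- simulate_tissue_cohort(n_per_group = c(BPH = 4, PCa = 3, mPCa = 3),
                               n_proteins = 80, n_markers = 10, seed = 13)
  c2 <- simulate_tissue_cohort(n_per_group = c(BPH = 4, PCa = 3, mPCa = 3),
                               n_proteins = 80, n_markers = 10, seed = 13)
  expect_identical(unclass(c1$quant), unclass(c2$quant))
  expect_identical(unclass(c1$cell_line), unclass(c2$cell_line))
  expect_identical(c1$truth_markers, c2$truth_markers)
})

test_that("the noiseless limit recovers the planted pattern for every protein", {
  cfg <- simulation_config(n_proteins = 200, noise_log10_sd = 0,
                           effect_log10 = 1,
                           pattern_frequencies = setNames(1, "dus"),
                           missing_rate_per_condition = rep(0, 4), seed = 3)
  st <- simulate_dose_response(cfg)
  prot <- setdiff(rownames(st$quant), st$spike_rows)
  pt <- pattern_table(st$quant[prot, ], st$design,
                      direction_params(fold_threshold = 5))  # < 10^effect
  expect_true(all(pt$pattern == "dus"))
})

test_that("spike rows are constant across samples before distortion", {
  cfg <- simulation_config(n_proteins = 50, seed = 21)
  st <- simulate_dose_response(cfg)
  spike <- unclass(st$quant)[st$spike_rows, ]
  expect_equal(stats::sd(log10(spike)), 0)

  # loading distortion scales whole columns, spike included, and the
  # normalization undoes it
  eff <- c(1, 0.5, 2, 1.25)
  st2 <- simulate_dose_response(cfg, sample_effects = eff)
  norm <- normalize_to_spike(st2$quant, st2$spike_rows)
  base <- normalize_to_spike(st$quant, st$spike_rows)
  expect_equal(unclass(norm), unclass(base), tolerance = 1e-9)
})

test_that("realized pattern frequencies follow the configured multinomial", {
  freqs <- setNames(c(0.5, 0.3, 0.2), c("sss", "uud", "ddd"))
  cfg <- simulation_config(n_proteins = 10000, pattern_frequencies = freqs,
                           missing_rate_per_condition = rep(0, 4), seed = 8)
  st <- simulate_dose_response(cfg)
  counts <- table(st$truth_patterns)
  for (code in names(freqs)) {
    expected <- 10000 * freqs[[code]]
    sigma <- sqrt(10000 * freqs[[code]] * (1 - freqs[[code]]))
    expect_lt(abs(counts[[code]] - expected), 3 * sigma)
  }
})

test_that("per-condition presence counts match the binomial expectation", {
  # rates tuned so expected per-condition counts of a 3341-protein union
  # are about 1540 / 1558 / 1668 / 1586
  target <- c(1540, 1558, 1668, 1586)
  cfg_rates <- 1 - target / 3341
  n <- 3400
  expected <- n * (1 - cfg_rates)
  sigma <- sqrt(n * (1 - cfg_rates) * cfg_rates)
  realized <- matrix(0, 20, 4)
  for (seed in 1:20) {
    cfg <- simulation_config(n_proteins = n,
                             missing_rate_per_condition = cfg_rates,
                             seed = seed)
    st <- simulate_dose_response(cfg)
    prot <- setdiff(rownames(st$quant), st$spike_rows)
    realized[seed, ] <- colSums(!is.na(unclass(st$quant)[prot, ]))
  }
  # average over seeds: 3-sigma bound on the per-seed binomial, tightened
  # by sqrt(20) for the mean
  for (j in 1:4) {
    expect_lt(abs(mean(realized[, j]) - expected[j]),
              3 * sigma[j] / sqrt(20))
  }
})

test_that("planted gene-set enrichment behaves at its limits", {
  cfg <- simulation_config(n_proteins = 400,
                           missing_rate_per_condition = rep(0, 4), seed = 5)
  st <- simulate_dose_response(cfg)

  # extreme enrichment with the set inside the class: ORA p equals the
  # minimal hypergeometric tail for full overlap
  gs <- simulate_gene_sets(n_terms = 1, set_size_range = c(8, 8),
                           n_enriched = 1, enrichment_factor = 1e12,
                           truth_patterns = st$truth_patterns, seed = 9)
  class_members <- names(st$truth_patterns)[st$truth_patterns == gs$target_pattern]
  expect_true(all(gs$gene_sets[[1]] %in% class_members))
  res <- ora(class_members, names(st$truth_patterns), gs$gene_sets)
  N <- length(st$truth_patterns)
  p_min <- stats::phyper(8 - 1, 8, N - 8, length(class_members),
                         lower.tail = FALSE)
  expect_equal(res$p_value, p_min, tolerance = 1e-12)

  expect_error(simulate_gene_sets(5, c(5, 10), 6, 2, st$truth_patterns, seed = 1),
               "n_enriched")
  expect_error(simulate_gene_sets(5, c(5, 10), 1, 2,
                                  setNames(character(0), character(0)), seed = 1),
               "empty universe")
})

test_that("a null tissue cohort yields no candidates; effects are recoverable", {
  for (seed in 1:5) {
    co <- simulate_tissue_cohort(n_per_group = c(BPH = 5, PCa = 5, mPCa = 5),
                                 n_proteins = 100, n_markers = 10,
                                 effect_log10 = 0, noise_log10_sd = 0.2,
                                 seed = seed)
    cand <- candidate_biomarkers(co$cell_line_patterns, co$quant, co$design,
                                 min_log10_fc = 0.5)
    expect_false(any(cand$passes))
  }

  co <- simulate_tissue_cohort(n_per_group = c(NAT = 4, BPH = 5, PCa = 5, mPCa = 5),
                               n_proteins = 150, n_markers = 15,
                               effect_log10 = 1, seed = 44)
  # the archetype is biphasic in the cell line: peak at the second-highest
  # dose, fall below baseline at the supraphysiologic dose
  arch <- names(co$truth_markers)[co$truth_markers == "androgen_biphasic_tumor_up"]
  expect_length(arch, 1)
  expect_equal(unname(co$cell_line_patterns[arch]), "uud")
  prof <- unclass(co$cell_line)[arch, ]
  expect_gt(prof["1.0nM"], prof["10nM"])
  expect_lt(prof["10nM"], prof["0nM"])
  expect_error(simulate_tissue_cohort(n_per_group = c(BPH = 2, PCa = 2),
                                      n_proteins = 10, n_markers = 8, seed = 1),
               "n_markers")
  expect_error(simulate_tissue_cohort(n_per_group = c(XXX = 3), seed = 1),
               "unknown group")
})
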