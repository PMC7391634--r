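test_that("genotype simulation is deterministic and respects dosage bounds", {
  g1 <- simulate_genotypes(50, 30, seed = 7)
  g2 <- simulate_genotypes(50, 30, seed = 7)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosage %in% 0:2))
  expect_error(simulate_genotypes(50, 10, maf_range = c(0, 0.6)), "maf_range")
  expect_error(simulate_genotypes(50, 10, ld_rho = 1), "ld_rho")
  expect_error(simulate_genotypes(1, 10), "n_samples")
})

test_that("independent variants are uncorrelated and HWE holds", {
  g <- simulate_genotypes(5000, 10, ld_rho = 0, ld_block_size = 1, seed = 11)
  cc <- abs(stats::cor(g$dosage))
  expect_lt(mean(cc[upper.tri(cc)]), 0.05)

  gh <- simulate_genotypes(10000, 1, maf_range = c(0.3, 0.3), seed = 3)
  counts <- table(factor(gh$dosage, levels = 0:2))
  expected <- c(0.49, 0.42, 0.09) * 10000
  se <- sqrt(expected * (1 - c(0.49, 0.42, 0.09)))
  expect_true(all(abs(counts - expected) < 3 * se))
})

test_that("LD blocks carry higher dosage correlation than between blocks", {
  g <- simulate_genotypes(2000, 20, ld_rho = 0.9, ld_block_size = 10,
                          maf_range = c(0.3, 0.4), seed = 5)
  r2 <- stats::cor(g$dosage)^2
  within <- r2[1:10, 1:10][upper.tri(r2[1:10, 1:10])]
  between <- r2[1:10, 11:20]
  expect_gt(mean(within), 0.3)
  expect_lt(mean(between), 0.02)
})

test_that("planted meQTL effects are recovered from the latent M-values", {
  ## noiseless limit: regression recovers the planted slope almost exactly
  cfg <- simulation_config(noise_sd = 0, batch_sd = 0, seed = 21)
  study <- simulate_study(cfg)
  mv <- beta_to_m(study$methylation$beta)["cg000001", ]
  ivs <- cfg$meqtl_effects$variant[cfg$meqtl_effects$cpg == "cg000001"]
  fit <- stats::lm(mv ~ study$genotypes$dosage[, ivs])
  expect_equal(unname(stats::coef(fit)[-1]), rep(0.8, 3), tolerance = 1e-6)

  ## stochastic recovery: slope within 3 SE of the planted value
  cfg2 <- simulation_config(
    n_cases = 250, n_controls = 250, chroms = "1", n_cpgs = 10,
    n_variants_per_chrom = 20, noise_sd = 1, batch_sd = 0,
    meqtl_effects = data.frame(cpg = "cg000001", variant = "var1_0001",
                               effect = 0.4),
    causal_cpg_effects = data.frame(cpg = character(0), design = character(0),
                                    effect = numeric(0)),
    n_chordee = 0, n_severe = 0, seed = 22)
  study2 <- simulate_study(cfg2)
  mv2 <- beta_to_m(study2$methylation$beta)["cg000001", ]
  fit2 <- summary(stats::lm(mv2 ~ study2$genotypes$dosage[, "var1_0001"]))
  expect_lt(abs(fit2$coefficients[2, 1] - 0.4), 3 * fit2$coefficients[2, 2])
})

test_that("simulated betas always lie strictly inside (0, 1)", {
  for (s in 1:3) {
    study <- simulate_study(simulation_config(n_cpgs = 50, seed = s,
                                              noise_sd = 2, batch_sd = 1))
    expect_true(all(study$methylation$beta > 0 & study$methylation$beta < 1))
  }
})

test_that("outcome labels reproduce the configured study structure exactly", {
  study <- simulate_study(simulation_config(seed = 1))
  ph <- study$phenotype
  expect_equal(sum(ph$hypospadias == 1), 45)
  expect_equal(sum(ph$hypospadias == 0), 46)
  expect_equal(sum(ph$chordee == 1, na.rm = TRUE), 21)
  expect_equal(sum(ph$severity == "severe", na.rm = TRUE), 9)
  expect_true(all(is.na(ph$chordee[ph$hypospadias == 0])))
  expect_true(all(is.na(ph$severity[ph$hypospadias == 0])))
  ## every severe case presents with chordee under the default nesting
  expect_true(all(ph$chordee[!is.na(ph$severity) & ph$severity == "severe"] == 1))
  tab <- phenotype_summary(ph)
  expect_equal(sum(tab$n), 45)
  distal_chordee <- tab[tab$location == "distal" & tab$chordee == 1, ]
  expect_equal(distal_chordee$n, 6)
  expect_equal(distal_chordee$pct, 13.3)
})

test_that("under null effects case labels are independent of methylation", {
  cors <- replicate(100, {
    cfg <- null_sim_config(n_cases = 10, n_controls = 10, n_cpgs = 5,
                           n_variants_per_chrom = 10, chroms = "1",
                           seed = sample.int(1e6, 1))
    study <- simulate_study(cfg)
    stats::cor(study$phenotype$hypospadias,
               study$methylation$beta["cg000001", study$phenotype$sample_id])
  })
  expect_lt(abs(mean(cors)), 3 * stats::sd(cors) / sqrt(length(cors)))
})

test_that("an extreme liability effect separates cases from controls", {
  ## true M varies through planted meQTLs; dosage levels make it discrete,
  ## so separation is up to boundary ties
  cfg <- simulation_config(
    n_cpgs = 20, n_variants_per_chrom = 20, chroms = "1",
    meqtl_effects = data.frame(cpg = "cg000001",
                               variant = c("var1_0001", "var1_0011"),
                               effect = 0.8),
    causal_cpg_effects = data.frame(cpg = "cg000001",
                                    design = "hypospadias_case_control",
                                    effect = 20),
    seed = 9)
  study <- simulate_study(cfg)
  m <- study$truth$m_true["cg000001", study$phenotype$sample_id]
  case <- study$phenotype$hypospadias == 1
  expect_gte(min(m[case]), max(m[!case]))
  expect_gt(mean(m[case]), mean(m[!case]) + 0.5)
})

test_that("summary-statistic fixtures carry exact ratios in the noiseless limit", {
  ss <- simulate_summary_stats(20, true_wald_ratios = 0.2,
                               outcome_noise_sd = 0, seed = 4)
  h <- harmonize_summary_stats(ss$exposure, ss$outcome)
  w <- run_wald_mr(h)
  expect_equal(w$estimate, rep(0.2, 20), tolerance = 1e-12)

  ## strand flips are undone exactly by harmonization
  ss_flip <- simulate_summary_stats(20, true_wald_ratios = 0.2,
                                    outcome_noise_sd = 0, flip_fraction = 0.5,
                                    seed = 4)
  w_flip <- run_wald_mr(harmonize_summary_stats(ss_flip$exposure, ss_flip$outcome))
  expect_equal(w_flip$estimate, w$estimate, tolerance = 1e-12)
  expect_true(any(harmonize_summary_stats(ss_flip$exposure,
                                          ss_flip$outcome)$action == "flipped"))

  ## palindromic variants are planted on request
  ss_pal <- simulate_summary_stats(10, palindromic_fraction = 0.5, seed = 4)
  expect_equal(sum(ss_pal$exposure$effect_allele == "A" &
                     ss_pal$exposure$other_allele == "T"), 5)
})
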