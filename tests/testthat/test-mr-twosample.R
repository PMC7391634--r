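genes_fixture <- data.frame(
  gene = sprintf("G%02d", 1:12), chrom = c(rep("1", 10), "2", "2"),
  start = c(1.0e6, 1.2e6, 1.45e6, 1.5e6, 1.9e6, 2.0e6, 2.1e6, 2.4e6, 2.6e6,
            3.0e6, 1.5e6, 1.6e6),
  end = c(1.05e6, 1.25e6, 1.5e6, 1.55e6, 1.95e6, 2.05e6, 2.15e6, 2.45e6,
          2.65e6, 3.05e6, 1.55e6, 1.65e6), stringsAsFactors = FALSE)

test_that("cis mapping uses inclusive 500 kb bounds on the right chromosome", {
  ## CpG at 1.5 Mb: window [1.0, 2.0] Mb
  hits <- map_cis_genes("1", 1.5e6, genes_fixture)
  expect_setequal(hits$gene, sprintf("G%02d", 1:6))
  ## a gene starting exactly at pos + window is included
  exact <- data.frame(gene = "edge", chrom = "1", start = 2.0e6, end = 2.2e6)
  expect_equal(nrow(map_cis_genes("1", 1.5e6, exact)), 1)
  ## and one base past the bound is not
  past <- data.frame(gene = "past", chrom = "1", start = 2.0e6 + 1, end = 2.2e6)
  expect_equal(nrow(map_cis_genes("1", 1.5e6, past)), 0)
  ## a gene entirely 600 kb away is excluded
  far <- data.frame(gene = "far", chrom = "1", start = 2.1e6, end = 2.15e6)
  expect_equal(nrow(map_cis_genes("1", 1.5e6, far)), 0)
  expect_warning(none <- map_cis_genes("X", 1.5e6, genes_fixture), "absent")
  expect_equal(nrow(none), 0)
  ## TSS mode only looks at starts
  tss <- map_cis_genes("1", 1.5e6, genes_fixture, mode = "tss")
  expect_setequal(tss$gene, sprintf("G%02d", 1:6))
})

test_that("a planted 7-of-12 cis fixture returns exactly the planted genes", {
  pos <- 5e6  # window [4.5, 5.5] Mb
  inside <- data.frame(gene = sprintf("in%d", 1:7), chrom = "1",
                       start = seq(4.5e6, 5.4e6, length.out = 7),
                       end = seq(4.5e6, 5.4e6, length.out = 7) + 2e4)
  outside <- data.frame(gene = sprintf("out%d", 1:5),
                        chrom = c("1", "1", "1", "2", "2"),
                        start = c(3.0e6, 5.6e6, 7.0e6, 5.0e6, 4.6e6),
                        end = c(3.1e6, 5.7e6, 7.1e6, 5.1e6, 4.7e6))
  hits <- map_cis_genes("1", pos, rbind(inside, outside))
  expect_setequal(hits$gene, inside$gene)
})

test_that("harmonization keeps, flips and drops records correctly", {
  ex <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "G"),
                   beta = c(0.5, 0.5, 0.5, 0.5), se = 0.05,
                   stringsAsFactors = FALSE)
  ou <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "G", "A", "C"),
                   other_allele = c("G", "A", "T", "G"),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = 0.02,
                   stringsAsFactors = FALSE)
  h <- harmonize_summary_stats(ex, ou)
  expect_equal(h$action, c("kept", "flipped", "dropped_palindromic",
                           "dropped_mismatch"))
  expect_equal(h$beta_outcome, c(0.1, -0.1, NA, NA))
  ## idempotence: re-harmonizing the aligned output changes nothing
  ou2 <- data.frame(variant_id = h$variant_id[1:2],
                    effect_allele = h$effect_allele[1:2],
                    other_allele = h$other_allele[1:2],
                    beta = h$beta_outcome[1:2], se = h$se_outcome[1:2],
                    stringsAsFactors = FALSE)
  h2 <- harmonize_summary_stats(ex[1:2, ], ou2)
  expect_equal(h2$action, c("kept", "kept"))
  expect_equal(h2$beta_outcome, h$beta_outcome[1:2])
  expect_error(harmonize_summary_stats(ex, transform(ou, variant_id = "zz")),
               "shared")
})

test_that("the Wald ratio follows its defining formulas", {
  w <- wald_ratio_mr(0.5, 0.04, 0.1, 0.05)
  expect_equal(w$estimate, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(w$p, 2 * stats::pnorm(-2))
  ## simultaneous sign flip leaves the estimate unchanged
  w2 <- wald_ratio_mr(-0.5, 0.04, -0.1, 0.05)
  expect_equal(w2$estimate, w$estimate)
  ## the second-order SE is never smaller than the first-order one
  w3 <- wald_ratio_mr(0.5, 0.04, 0.1, 0.05, second_order = TRUE)
  expect_gte(w3$se, w$se)
  expect_error(wald_ratio_mr(0, 0.04, 0.1, 0.05), "zero")
})

test_that("stochastic fixtures recover the planted ratio with ~5% null rejections", {
  ss <- simulate_summary_stats(300, true_wald_ratios = 0.3, seed = 20)
  w <- run_wald_mr(harmonize_summary_stats(ss$exposure, ss$outcome))
  mc_se <- stats::sd(w$estimate) / sqrt(nrow(w))
  expect_lt(abs(mean(w$estimate) - 0.3), 3 * mc_se)

  ss0 <- simulate_summary_stats(300, true_wald_ratios = 0, seed = 21)
  w0 <- run_wald_mr(harmonize_summary_stats(ss0$exposure, ss0$outcome))
  expect_lt(abs(mean(w0$significant) - 0.05),
            2.576 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("summary-level Wald ratio equals individual-level 2SLS when just-identified", {
  set.seed(22)
  n <- 150
  g <- stats::rbinom(n, 2, 0.3)
  m <- 0.5 * g + stats::rnorm(n)
  y <- 0.3 * m + stats::rnorm(n)
  bx <- stats::coef(summary(stats::lm(m ~ g)))[2, 1:2]
  by <- stats::coef(summary(stats::lm(y ~ g)))[2, 1:2]
  w <- wald_ratio_mr(bx[1], bx[2], by[1], by[2])
  fit <- fit_2sls(m, y, cbind(g))
  expect_equal(w$estimate, fit$estimate, tolerance = 1e-8)
})
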