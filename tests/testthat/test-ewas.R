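test_that("an unadjusted scan reproduces the equal-variance two-sample t-test", {
  m <- toy_methylation(5, 20, seed = 1)
  y <- rep(0:1, each = 10)
  res <- run_ewas(m, toy_phenotype(y), "hypospadias_case_control")
  for (i in seq_len(5)) {
    b <- m$beta[res$probe_id[i], ]
    tt <- stats::t.test(b[y == 1], b[y == 0], var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$effect[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
  ## sign convention: effect = case mean - comparison mean on this scale,
  ## while the reported delta_beta is comparison - case
  expect_equal(res$delta_beta, -res$effect, tolerance = 1e-12)
})

test_that("a null scan is calibrated", {
  set.seed(2)
  scans <- lapply(1:5, function(i) {
    m <- toy_methylation(1000, 60, seed = NULL)
    run_ewas(m, toy_phenotype(rep(0:1, 30)), "hypospadias_case_control")
  })
  frac <- mean(unlist(lapply(scans, function(r) r$p)) < 0.05)
  expect_lt(abs(frac - 0.05), 2.576 * sqrt(0.05 * 0.95 / 5000))
  lambdas <- vapply(scans, function(r) attr(r, "lambda"), 0)
  expect_lt(abs(mean(lambdas) - 1), 0.1)
})

test_that("a planted group shift ranks first and carries the printed-style delta", {
  set.seed(3)
  hits <- replicate(20, {
    m <- toy_methylation(200, 91, seed = NULL)
    y <- rep(c(1, 0), c(45, 46))
    b <- m$beta
    shifted <- beta_to_m(b["cg000001", ]) + 1 * y  # ~0.15 beta shift mid-range
    b["cg000001", ] <- m_to_beta(shifted)
    mm <- methylation_matrix(b, m$manifest)
    res <- run_ewas(mm, toy_phenotype(y), "hypospadias_case_control")
    res$probe_id[1] == "cg000001"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("adding covariates orthogonal to the groups leaves effects unchanged", {
  m <- toy_methylation(30, 24, seed = 4)
  y <- rep(0:1, 12)
  set.seed(5)
  raw <- cbind(stats::rnorm(24), stats::rnorm(24))
  ortho <- qr.resid(qr(cbind(1, y)), raw)
  rownames(ortho) <- colnames(m$beta)
  r0 <- run_ewas(m, toy_phenotype(y), "hypospadias_case_control")
  r1 <- run_ewas(m, toy_phenotype(y), "hypospadias_case_control",
                 covariates = ortho)
  expect_equal(r1$effect[match(r0$probe_id, r1$probe_id)], r0$effect,
               tolerance = 1e-10)
})

test_that("the scan is invariant to sample permutation", {
  m <- toy_methylation(20, 16, seed = 6)
  y <- rep(0:1, 8)
  r0 <- run_ewas(m, toy_phenotype(y), "hypospadias_case_control")
  set.seed(7)
  perm <- sample(16)
  m2 <- methylation_matrix(m$beta[, perm], m$manifest)
  r1 <- run_ewas(m2, toy_phenotype(y[perm], ids = colnames(m$beta)[perm]),
                 "hypospadias_case_control")
  expect_equal(r1$p[match(r0$probe_id, r1$probe_id)], r0$p, tolerance = 1e-12)
})

test_that("constant probes get NA and are excluded from the FDR", {
  m <- toy_methylation(10, 12, seed = 8)
  b <- m$beta
  b["cg000004", ] <- 0.5
  mm <- methylation_matrix(b, m$manifest)
  expect_warning(res <- run_ewas(mm, toy_phenotype(rep(0:1, 6)),
                                 "hypospadias_case_control"), "constant")
  expect_true(is.na(res$p[res$probe_id == "cg000004"]))
  expect_true(is.na(res$q[res$probe_id == "cg000004"]))
  expect_equal(sum(!is.na(res$q)), 9)
})

test_that("delta_beta reports signed differences and percentages", {
  d <- delta_beta(c(0.591, 0.392, 0.3), c(0.748, 0.506, 0.3))
  expect_equal(d$delta_beta, c(0.157, 0.114, 0), tolerance = 1e-12)
  expect_equal(d$percent, c(15.7, 11.4, 0), tolerance = 1e-10)
  expect_error(delta_beta(1.2, 0.5), "within")
})

test_that("genomic inflation matches its defining identities", {
  expect_equal(genomic_inflation(0.5), 1)
  set.seed(9)
  p <- stats::runif(1e5)
  expect_lt(abs(genomic_inflation(p) - 1), 0.02)
  ## doubling the chi-squares roughly doubles lambda
  p2 <- stats::pchisq(2 * stats::qchisq(p, 1, lower.tail = FALSE), 1,
                      lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p2) - 2), 0.05)
  expect_error(genomic_inflation(numeric(0)), "p-values")
  expect_error(genomic_inflation(0), "p-values")
})

test_that("BH q-values match hand-computed and brute-force references", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(10)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  ## NAs propagate and do not affect the rest
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p), c(0.02, NA, 0.04))
})

test_that("covariate tuning selects the inflation-controlling set", {
  set.seed(11)
  n <- 60
  y <- rep(0:1, n / 2)
  batch <- ifelse(stats::runif(n) < 0.85, y, 1 - y)
  m <- matrix(stats::rnorm(400 * n, sd = 0.5), 400, n) +
    outer(stats::rnorm(400, sd = 0.5), batch)
  beta <- m_to_beta(m)
  dimnames(beta) <- list(sprintf("cg%06d", 1:400), sprintf("S%03d", 1:n))
  mm <- methylation_matrix(beta, toy_manifest(rownames(beta)))
  svs <- estimate_surrogate_variables(mm, y, n_perm = 60)
  tuned <- tune_covariates(mm, toy_phenotype(y), "hypospadias_case_control",
                           list(none = NULL, sv = svs))
  expect_equal(tuned$selected, "sv")
  lam <- tuned$lambda_trace$lambda
  expect_gt(lam[1], 1.5)
  expect_lt(abs(lam[2] - 1), abs(lam[1] - 1))

  ## single candidate comes back unchanged; exact ties prefer input order
  single <- tune_covariates(mm, toy_phenotype(y), "hypospadias_case_control",
                            list(only = svs))
  expect_equal(single$selected, "only")
  tie <- tune_covariates(mm, toy_phenotype(y), "hypospadias_case_control",
                         list(a = NULL, b = NULL))
  expect_equal(tie$selected, "a")
})

test_that("suggestive selection respects per-design thresholds and dedupes", {
  fake <- function(design, q) {
    structure(data.frame(probe_id = sprintf("cg%06d", seq_along(q)),
                         chrom = "1", pos = seq_along(q), case_mean = 0.5,
                         comparison_mean = 0.5, delta_beta = 0, effect = 0,
                         se = 1, t = 0, p = q / 2, q = q,
                         stringsAsFactors = FALSE),
              class = c("ewas_result", "data.frame"),
              design = ewas_design(design))
  }
  r1 <- fake("hypospadias_case_control", c(0.05, 0.15, 0.25, 0.5))
  r2 <- fake("chordee_case_only", c(0.10, 0.18, 0.9, 0.9))
  sel <- select_suggestive(list(r1, r2))
  expect_equal(sum(sel$design == "hypospadias_case_control"), 2)  # q < 0.20
  expect_equal(sum(sel$design == "chordee_case_only"), 1)         # q < 0.15
  ## same result listed twice collapses by (probe, design)
  expect_equal(nrow(select_suggestive(list(r1, r1))), 2)
  ## nothing below threshold gives an empty, well-formed table
  r3 <- fake("severity_case_only", c(0.5, 0.8))
  expect_equal(nrow(select_suggestive(r3)), 0)
})

test_that("candidate lookup classifies absent, failed-QC and tested CpGs", {
  results <- data.frame(probe_id = sprintf("cg%06d", 1:7),
                        effect = stats::rnorm(7), p = stats::runif(7),
                        stringsAsFactors = FALSE)
  manifest <- toy_manifest(sprintf("cg%06d", 1:12))
  candidates <- sprintf("cg%06d", 1:14)  # 13, 14 absent from the array
  out <- lookup_candidates(results, candidates, manifest)
  expect_equal(as.vector(table(out$status)[c("absent_from_array", "failed_qc",
                                             "tested")]),
               c(2L, 5L, 7L))
  expect_true(all(!is.na(out$p[out$status == "tested"])))
  expect_true(all(is.na(out$p[out$status != "tested"])))
  expect_error(lookup_candidates(results, character(0), manifest), "empty")
})
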