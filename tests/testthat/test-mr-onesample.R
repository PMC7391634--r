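test_that("just-identified 2SLS equals the instrument ratio exactly", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    g <- stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5))
    m <- 0.5 * g + stats::rnorm(n)
    y <- 0.3 * m + stats::rnorm(n)
    fit <- fit_2sls(m, y, cbind(g))
    expect_equal(fit$estimate, stats::cov(g, y) / stats::cov(g, m),
                 tolerance = 1e-10)
  }
})

test_that("2SLS removes confounding bias that contaminates naive OLS", {
  set.seed(2)
  gamma <- sqrt(0.5 / 2.1)  # first-stage R2 ~ 0.2 with 5 instruments
  ests <- naive <- numeric(60)
  for (i in seq_len(60)) {
    n <- 500
    g <- matrix(stats::rbinom(n * 5, 2, 0.3), n, 5)
    u <- stats::rnorm(n)
    m <- g %*% rep(gamma, 5) + u + stats::rnorm(n)
    y <- 0.3 * m + 0.8 * u + stats::rnorm(n)
    fit <- fit_2sls(as.numeric(m), as.numeric(y), g)
    ests[i] <- fit$estimate
    naive[i] <- stats::coef(stats::lm(y ~ m))[2]
  }
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.3), 3 * mc_se)
  expect_lt(abs(mean(ests) - 0.3), 0.5 * abs(mean(naive) - 0.3))
})

test_that("null p-values are uniform with strong instruments", {
  set.seed(3)
  ps <- replicate(300, {
    n <- 200
    g <- matrix(stats::rbinom(n * 3, 2, 0.3), n, 3)
    u <- stats::rnorm(n)
    m <- g %*% c(0.5, 0.5, 0.5) + u + stats::rnorm(n)
    y <- 0.8 * u + stats::rnorm(n)
    fit_2sls(as.numeric(m), as.numeric(y), g)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("first-stage diagnostics match the textbook F identity", {
  set.seed(4)
  n <- 80
  g <- matrix(stats::rbinom(n * 4, 2, 0.4), n, 4)
  m <- g %*% stats::runif(4, 0.2, 0.5) + stats::rnorm(n)
  d <- first_stage_diagnostics(as.numeric(m), g)
  k <- 4
  f_textbook <- (d$r_squared / k) / ((1 - d$r_squared) / (n - k - 1))
  expect_equal(d$F, f_textbook, tolerance = 1e-10)
  expect_equal(nrow(d$per_instrument), 4)
  ## per-instrument t matches lm
  fit <- summary(stats::lm(m ~ g))$coefficients
  expect_equal(d$per_instrument$t, unname(fit[2:5, 3]), tolerance = 1e-10)
})

test_that("a noiseless first stage caps F and flags nothing weak", {
  set.seed(5)
  g <- stats::rbinom(50, 2, 0.4)
  m <- 0.7 * g          # exact first stage
  y <- 0.2 * m + stats::rnorm(50)
  fit <- fit_2sls(m, y, cbind(g))
  expect_true(fit$first_stage$capped)
  expect_equal(fit$first_stage$F, 1e12)
  expect_false("weak_instrument" %in% fit$flags)
})

test_that("irrelevant instruments average F near one and are flagged weak", {
  set.seed(6)
  fs <- replicate(100, {
    g <- matrix(stats::rbinom(60 * 2, 2, 0.3), 60, 2)
    m <- stats::rnorm(60)
    first_stage_diagnostics(m, g)$F
  })
  expect_lt(abs(mean(fs) - 1), 0.3)
  set.seed(7)
  g <- matrix(stats::rbinom(200 * 2, 2, 0.3), 200, 2)
  m <- stats::rnorm(200)
  y <- stats::rnorm(200)
  fit <- fit_2sls(m, y, g)
  expect_true("weak_instrument" %in% fit$flags)
})

test_that("estimates are invariant to instrument recoding and null additions", {
  set.seed(8)
  n <- 100
  g1 <- stats::rbinom(n, 2, 0.3)
  g2 <- stats::rbinom(n, 2, 0.4)
  m <- 0.6 * g1            # noiseless exposure
  y <- 0.25 * m            # noiseless outcome
  base <- fit_2sls(m, y, cbind(g1))
  ## dosage flip g -> 2 - g
  flipped <- fit_2sls(m, y, cbind(2 - g1))
  expect_equal(flipped$estimate, base$estimate, tolerance = 1e-10)
  ## adding an instrument with zero first-stage coefficient
  extra <- fit_2sls(m, y, cbind(g1, g2))
  expect_equal(extra$estimate, base$estimate, tolerance = 1e-8)
})

test_that("degenerate instrument matrices raise informative errors", {
  set.seed(9)
  g <- stats::rbinom(40, 2, 0.3)
  m <- 0.5 * g + stats::rnorm(40)
  y <- stats::rnorm(40)
  gg <- cbind(a = g, b = g)
  expect_error(fit_2sls(m, y, gg), "collinear")
  expect_error(fit_2sls(m, y[1:10], cbind(g)), "same samples")
})

test_that("classical SEs use observed-exposure residuals", {
  ## against a hand-rolled 2SLS with the standard formula
  set.seed(10)
  n <- 120
  g <- matrix(stats::rbinom(n * 3, 2, 0.3), n, 3)
  u <- stats::rnorm(n)
  m <- g %*% c(0.4, 0.3, 0.5) + u + stats::rnorm(n)
  y <- 0.3 * m + u + stats::rnorm(n)
  fit <- fit_2sls(as.numeric(m), as.numeric(y), g)
  z <- cbind(1, g)
  mhat <- z %*% solve(crossprod(z), crossprod(z, m))
  x2 <- cbind(1, mhat)
  b <- solve(crossprod(x2), crossprod(x2, y))
  res <- y - cbind(1, m) %*% b
  vc <- as.numeric(crossprod(res) / (n - 2)) * solve(crossprod(x2))
  expect_equal(fit$estimate, b[2, 1], tolerance = 1e-10)
  expect_equal(fit$se, sqrt(vc[2, 2]), tolerance = 1e-10)
  ## model-object methods
  expect_equal(unname(coef(fit)), fit$estimate)
  ci <- confint(fit)
  expect_lt(ci[1], fit$estimate)
  expect_gt(ci[2], fit$estimate)
  expect_output(print(summary(fit)), "First-stage")
})
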