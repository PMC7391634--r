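#' One-sample two-stage least squares Mendelian randomization
#'
#' Estimates the causal effect of a CpG's methylation (M-values) on a binary
#' outcome using genetic instruments. Stage one regresses the exposure on
#' the instrument dosages (plus covariates); stage two regresses the outcome
#' on the fitted exposure (plus covariates) as a linear probability model.
#' The standard error is the classical homoskedastic 2SLS one: residuals are
#' computed from the \emph{observed} exposure (y - X beta-hat), not the
#' fitted exposure, and the two-sided p-value uses the t distribution with
#' n - k degrees of freedom. With a single instrument the estimate equals
#' the ratio \code{cov(G, Y) / cov(G, M)} exactly.
#'
#' @param exposure Numeric vector of M-values (named by sample id
#'   recommended).
#' @param outcome Numeric (typically 0/1) outcome vector.
#' @param instruments n x k matrix of instrument dosages (or a
#'   [genotype_matrix()]).
#' @param covariates Optional n x q covariate matrix included in both
#'   stages.
#' @param robust Use heteroskedasticity-robust (HC0-type) 2SLS standard
#'   errors instead of the classical ones.
#' @param weak_f_threshold First-stage F below which the fit is flagged
#'   weak (default 10).
#' @return An object of class \code{"mr_2sls"} with components
#'   \code{estimate}, \code{se}, \code{statistic}, \code{df},
#'   \code{p.value}, \code{n}, \code{n_instruments}, \code{first_stage}
#'   (see [first_stage_diagnostics()]) and \code{flags}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{confint}.
#' @export
fit_2sls <- function(exposure, outcome, instruments, covariates = NULL,
                     robust = FALSE, weak_f_threshold = 10) {
  if (inherits(instruments, "genotype_matrix")) {
    g <- instruments$dosage
  } else {
    g <- as.matrix(instruments)
  }
  if (is.null(colnames(g))) colnames(g) <- paste0("IV", seq_len(ncol(g)))
  ids <- NULL
  if (!is.null(names(exposure)) && !is.null(rownames(g))) {
    ids <- intersect(names(exposure), rownames(g))
    outcome <- if (!is.null(names(outcome))) outcome[ids]
               else outcome[match(ids, names(exposure))]
    exposure <- exposure[ids]
    g <- g[ids, , drop = FALSE]
  }
  n <- length(exposure)
  if (length(outcome) != n || nrow(g) != n)
    stop("exposure, outcome and instruments must cover the same samples")
  if (ncol(g) < 1) stop("at least one instrument is required")

  xc <- design_with_intercept(n, covariates, ids)
  z <- cbind(xc, g)
  qz <- qr(z)
  if (qz$rank < ncol(z)) {
    drop_idx <- qz$pivot[seq.int(qz$rank + 1, ncol(z))]
    stop("collinear instruments/covariates: ",
         paste(colnames(z)[drop_idx], collapse = ", "))
  }
  mhat <- qr.fitted(qz, exposure)

  diag1 <- first_stage_diagnostics(exposure, g, covariates = covariates)
  x2 <- cbind(xc[, 1, drop = FALSE], exposure = mhat, xc[, -1, drop = FALSE])
  qx2 <- qr(x2)
  if (qx2$rank < ncol(x2))
    stop("second-stage design is rank deficient (zero first-stage fit?)")
  bhat <- qr.coef(qx2, outcome)
  k <- ncol(x2)
  df <- n - k
  x2_obs <- x2
  x2_obs[, "exposure"] <- exposure
  resid <- as.numeric(outcome - x2_obs %*% bhat)
  xtx_inv <- chol2inv(qr.R(qx2))
  if (robust) {
    xi <- x2 %*% xtx_inv
    vc <- crossprod(xi * resid) * n / df
  } else {
    vc <- sum(resid^2) / df * xtx_inv
  }
  dimnames(vc) <- list(colnames(x2), colnames(x2))
  est <- unname(bhat["exposure"])
  se <- sqrt(vc["exposure", "exposure"])
  tstat <- est / se

  flags <- character(0)
  if (is.finite(diag1$F) && diag1$F < weak_f_threshold)
    flags <- c(flags, "weak_instrument")
  structure(list(estimate = est, se = se, statistic = tstat, df = df,
                 p.value = 2 * stats::pt(-abs(tstat), df), n = n,
                 n_instruments = ncol(g), coefficients = bhat, vcov = vc,
                 residuals = resid, first_stage = diag1, flags = flags,
                 call = match.call()),
            class = "mr_2sls")
}

#' First-stage instrument-strength diagnostics
#'
#' Joint F statistic for the instruments in the first-stage regression of
#' the exposure on instruments plus covariates (the partial F given the
#' covariates), the corresponding partial R-squared, and per-instrument
#' partial t statistics. An essentially perfect first-stage fit caps F at
#' \code{f_cap} and flags the fit strong.
#'
#' @inheritParams fit_2sls
#' @param f_cap Cap for a numerically infinite F (default 1e12).
#' @return list(F, r_squared, df1, df2, p, per_instrument =
#'   data.frame(instrument, estimate, se, t), capped).
#' @export
first_stage_diagnostics <- function(exposure, instruments, covariates = NULL,
                                    f_cap = 1e12) {
  g <- if (inherits(instruments, "genotype_matrix")) instruments$dosage
       else as.matrix(instruments)
  if (is.null(colnames(g))) colnames(g) <- paste0("IV", seq_len(ncol(g)))
  ids <- NULL
  if (!is.null(names(exposure)) && !is.null(rownames(g))) {
    ids <- intersect(names(exposure), rownames(g))
    exposure <- exposure[ids]
    g <- g[ids, , drop = FALSE]
  }
  n <- length(exposure)
  x0 <- design_with_intercept(n, covariates, ids)
  x1 <- cbind(x0, g)
  q0 <- qr(x0)
  q1 <- qr(x1)
  if (q1$rank < ncol(x1)) stop("first-stage design is rank deficient")
  rss0 <- sum(qr.resid(q0, exposure)^2)
  rss1 <- sum(qr.resid(q1, exposure)^2)
  k <- ncol(g)
  df2 <- n - ncol(x1)
  r2 <- if (rss0 > 0) (rss0 - rss1) / rss0 else 0
  capped <- rss1 <= max(1e-12 * rss0, 1e-300)
  f <- if (capped) f_cap else ((rss0 - rss1) / k) / (rss1 / df2)
  coefs <- qr.coef(q1, exposure)
  xtx_inv <- chol2inv(qr.R(q1))
  ses <- sqrt(pmax(rss1, 0) / df2 * diag(xtx_inv))
  iv_idx <- seq.int(ncol(x0) + 1, ncol(x1))
  per <- data.frame(instrument = colnames(g),
                    estimate = unname(coefs[iv_idx]),
                    se = unname(ses[iv_idx]),
                    t = unname(coefs[iv_idx] / ses[iv_idx]),
                    stringsAsFactors = FALSE)
  list(F = f, r_squared = r2, df1 = k, df2 = df2,
       p = stats::pf(f, k, df2, lower.tail = FALSE),
       per_instrument = per, capped = capped)
}

#' @export
print.mr_2sls <- function(x, ...) {
  cat("Two-stage least squares Mendelian randomization\n")
  cat(sprintf("  n = %d, instruments = %d, first-stage F = %.2f (R2 = %.3f)%s\n",
              x$n, x$n_instruments, x$first_stage$F, x$first_stage$r_squared,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  cat(sprintf("  causal estimate = %.4g (SE %.4g), t = %.3f, df = %d, p = %.3g\n",
              x$estimate, x$se, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
summary.mr_2sls <- function(object, ...) {
  structure(object, class = c("summary.mr_2sls", class(object)))
}

#' @export
print.summary.mr_2sls <- function(x, ...) {
  print.mr_2sls(x)
  cat("\nFirst-stage per-instrument coefficients:\n")
  print.data.frame(x$first_stage$per_instrument, digits = 3)
  invisible(x)
}

#' @export
coef.mr_2sls <- function(object, ...) c(exposure = object$estimate)

#' @export
vcov.mr_2sls <- function(object, ...) object$vcov

#' @export
confint.mr_2sls <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- stats::qt(c(a, 1 - a), object$df)
  out <- matrix(object$estimate + q * object$se, 1, 2,
                dimnames = list("exposure",
                                paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")))
  out
}
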