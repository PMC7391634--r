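#' Define an EWAS design
#'
#' The three designs of the study layout: hypospadias cases versus
#' unaffected controls, and two case-only comparisons (chordee present vs
#' absent; severe vs moderate). The suggestive FDR threshold defaults to
#' 0.20 for the larger case-control scan and 0.15 for the smaller case-only
#' scans, the stricter case-only threshold limiting false positives driven
#' by the small comparison groups.
#'
#' @param name One of \code{"hypospadias_case_control"},
#'   \code{"chordee_case_only"}, \code{"severity_case_only"}.
#' @param fdr_threshold Suggestive FDR threshold; NULL for the design
#'   default.
#' @return An object of class \code{"ewas_design"}.
#' @export
ewas_design <- function(name = c("hypospadias_case_control", "chordee_case_only",
                                 "severity_case_only"), fdr_threshold = NULL) {
  name <- match.arg(name)
  fdr_threshold <- fdr_threshold %||%
    if (name == "hypospadias_case_control") 0.20 else 0.15
  labels <- switch(name,
    hypospadias_case_control = c(case = "hypospadias case", comparison = "control"),
    chordee_case_only = c(case = "chordee present", comparison = "chordee absent"),
    severity_case_only = c(case = "severe", comparison = "moderate"))
  structure(list(name = name, fdr_threshold = fdr_threshold, labels = labels),
            class = "ewas_design")
}

## 0/1 response named by sample id for a design; 1 = case-labelled group
design_response <- function(phenotype, design) {
  y <- switch(design$name,
    hypospadias_case_control = stats::setNames(phenotype$hypospadias,
                                               phenotype$sample_id),
    chordee_case_only = {
      cases <- phenotype[phenotype$hypospadias == 1, ]
      stats::setNames(cases$chordee, cases$sample_id)
    },
    severity_case_only = {
      cases <- phenotype[phenotype$hypospadias == 1, ]
      stats::setNames(as.integer(cases$severity == "severe"), cases$sample_id)
    })
  y[!is.na(y)]
}

#' Per-CpG association scan for one design
#'
#' Ordinary least squares of methylation (beta values by default) on the
#' group indicator plus covariates, probe by probe, with classical
#' (homoskedastic) standard errors and two-sided t p-values. A positive
#' effect means higher methylation in the case-labelled group. Raw group
#' mean betas and \code{delta_beta = comparison mean - case mean} are
#' reported unadjusted. Probes with zero variance are returned with NA
#' statistics and excluded from the FDR correction.
#'
#' @param m A [methylation_matrix()].
#' @param phenotype Phenotype table (see [simulate_outcome()] for the
#'   layout).
#' @param design An [ewas_design()] or its name.
#' @param covariates Optional samples x q covariate matrix (sample ids as
#'   rownames recommended).
#' @param values \code{"beta"} (default) or \code{"m"} as the regression
#'   response; group means are always reported on the beta scale.
#' @param robust Use heteroskedasticity-robust (HC1) standard errors.
#' @return A data.frame of class \code{"ewas_result"} sorted by p-value with
#'   columns probe_id, chrom, pos, n_case, n_comparison, case_mean,
#'   comparison_mean, delta_beta, effect, se, t, p, q; attributes carry the
#'   design, genomic-inflation lambda and covariate names.
#' @export
run_ewas <- function(m, phenotype, design = "hypospadias_case_control",
                     covariates = NULL, values = c("beta", "m"), robust = FALSE) {
  stopifnot(inherits(m, "methylation_matrix"))
  values <- match.arg(values)
  if (is.character(design)) design <- ewas_design(design)
  y <- design_response(phenotype, design)
  ids <- intersect(colnames(m$beta), names(y))
  if (length(ids) < 4) stop("too few phenotyped samples for this design")
  y <- y[ids]
  if (min(table(y)) < 2) stop("each comparison group needs at least two samples")

  beta <- m$beta[, ids, drop = FALSE]
  resp <- t(if (values == "m") beta_to_m(beta) else beta)
  xc <- design_with_intercept(length(ids), covariates, ids)
  x <- cbind(xc[, 1, drop = FALSE], group = y, xc[, -1, drop = FALSE])
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("design plus covariates is rank deficient")

  coefs <- qr.coef(qx, resp)
  res <- qr.resid(qx, resp)
  df <- length(ids) - ncol(x)
  xtx_inv <- chol2inv(qr.R(qx))
  if (robust) {
    ## HC1 sandwich SE for the group coefficient, probe by probe
    h <- (x %*% xtx_inv)[, 2]
    se <- sqrt(colSums(h^2 * res^2) * length(ids) / df)
  } else {
    se <- sqrt(colSums(res^2) / df * xtx_inv[2, 2])
  }
  eff <- coefs[2, ]
  tested <- apply(resp, 2, stats::var) > 0 & se > 0
  tstat <- ifelse(tested, eff / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df)
  if (any(!tested))
    warning(sum(!tested), " constant probe(s) returned NA and were excluded from FDR")

  case_mean <- rowMeans(beta[, y == 1, drop = FALSE])
  comparison_mean <- rowMeans(beta[, y == 0, drop = FALSE])
  q <- bh_fdr(p)
  out <- data.frame(
    probe_id = rownames(beta),
    chrom = m$manifest$chrom[match(rownames(beta), m$manifest$probe_id)],
    pos = m$manifest$pos[match(rownames(beta), m$manifest$probe_id)],
    case_mean = case_mean, comparison_mean = comparison_mean,
    delta_beta = comparison_mean - case_mean,
    effect = ifelse(tested, eff, NA_real_), se = ifelse(tested, se, NA_real_),
    t = tstat, p = p, q = q, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out,
            class = c("ewas_result", "data.frame"),
            design = design, n_case = sum(y == 1), n_comparison = sum(y == 0),
            lambda = genomic_inflation(pmax(p[tested], 1e-300)),
            values = values,
            covariate_names = colnames(x)[-(1:2)])
}

#' @export
print.ewas_result <- function(x, n = 6, ...) {
  d <- attr(x, "design")
  cat("EWAS:", d$name, sprintf("(%d %s vs %d %s)\n", attr(x, "n_case"),
      d$labels["case"], attr(x, "n_comparison"), d$labels["comparison"]))
  cat(sprintf("  %d probes tested | genomic inflation lambda = %.3f | covariates: %s\n",
              sum(!is.na(x$p)), attr(x, "lambda"),
              if (length(attr(x, "covariate_names")))
                paste(attr(x, "covariate_names"), collapse = ", ") else "none"))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 3)
  invisible(x)
}

#' Signed methylation difference between comparison and case group means
#'
#' Reported the way published EWAS tables print it: \code{delta = comparison
#' mean - case mean}, so a case group with lower methylation gives a
#' positive delta, plus the absolute difference as a percentage.
#'
#' @param case_mean,comparison_mean Group mean beta values in \code{[0, 1]}
#'   (vectorized).
#' @return data.frame(delta_beta, percent).
#' @export
delta_beta <- function(case_mean, comparison_mean) {
  if (any(case_mean < 0 | case_mean > 1, na.rm = TRUE) ||
      any(comparison_mean < 0 | comparison_mean > 1, na.rm = TRUE))
    stop("group means must lie within [0, 1]")
  d <- comparison_mean - case_mean
  data.frame(delta_beta = d, percent = 100 * abs(d))
}

#' Genomic inflation factor of a p-value set
#'
#' \code{lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)}: the median
#' association chi-square relative to its null median (0.4549364). Close to
#' 1 for a well-calibrated scan; above 1 under confounding or batch
#' structure.
#'
#' @param pvalues Numeric p-values in \code{(0, 1]}; NAs dropped.
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (!length(p)) stop("no finite p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values (\code{stats::p.adjust(method = "BH")}) computed
#' over the non-missing p-values only; NAs are propagated.
#'
#' @param pvalues Numeric p-values in \code{[0, 1]}, possibly with NAs.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Choose the covariate set that best controls genomic inflation
#'
#' Runs the scan once per candidate covariate set and selects the set whose
#' inflation factor is closest to 1; ties are broken in favour of fewer
#' covariates, then input order. The full lambda trace is returned.
#'
#' @inheritParams run_ewas
#' @param candidate_sets Named list of covariate matrices (use NULL for the
#'   unadjusted model).
#' @return list(selected = name, covariates, result = the winning
#'   [run_ewas()] result, lambda_trace = data.frame(name, n_covariates,
#'   lambda)).
#' @export
tune_covariates <- function(m, phenotype, design, candidate_sets,
                            values = c("beta", "m")) {
  values <- match.arg(values)
  if (!length(candidate_sets)) stop("at least one candidate covariate set is required")
  if (is.null(names(candidate_sets)))
    names(candidate_sets) <- paste0("set", seq_along(candidate_sets))
  fits <- lapply(candidate_sets, function(cov)
    run_ewas(m, phenotype, design, covariates = cov, values = values))
  trace <- data.frame(
    name = names(candidate_sets),
    n_covariates = vapply(candidate_sets, function(cov)
      if (is.null(cov)) 0L else ncol(as.matrix(cov)), 0L),
    lambda = vapply(fits, function(f) attr(f, "lambda"), 0),
    stringsAsFactors = FALSE)
  best <- order(abs(trace$lambda - 1), trace$n_covariates,
                seq_len(nrow(trace)))[1]
  list(selected = trace$name[best], covariates = candidate_sets[[best]],
       result = fits[[best]], lambda_trace = trace)
}

#' Select suggestive CpGs across designs
#'
#' Filters each scan at its design-level FDR threshold and stacks the
#' results, annotated with the design of origin and deduplicated by
#' (probe, design).
#'
#' @param results A single [run_ewas()] result or a list of them.
#' @return data.frame with a \code{design} column plus the result columns.
#' @export
select_suggestive <- function(results) {
  if (inherits(results, "ewas_result")) results <- list(results)
  picked <- lapply(results, function(r) {
    thr <- attr(r, "design")$fdr_threshold
    rows <- as.data.frame(r)[!is.na(r$q) & r$q < thr, , drop = FALSE]
    if (nrow(rows)) cbind(design = attr(r, "design")$name, rows,
                          stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, picked)
  if (is.null(out))
    out <- cbind(design = character(0),
                 as.data.frame(results[[1]])[0, , drop = FALSE])
  out <- out[!duplicated(out[, c("probe_id", "design")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up previously reported candidate CpGs in a scan
#'
#' Classifies each candidate CpG as absent from the array (not in the
#' manifest), failed QC (present on the array but removed by the probe
#' filters or otherwise untested), or tested - reporting effect and p-value
#' for the tested ones.
#'
#' @param results An [run_ewas()] result.
#' @param candidate_cpgs Character vector of probe ids to look up.
#' @param manifest Full pre-QC probe manifest (data.frame with
#'   \code{probe_id}).
#' @param qc_report Optional QC report (from [run_qc()] or
#'   [filter_probes()]) used to label removals.
#' @return data.frame(probe_id, status, effect, p) with status in
#'   \{absent_from_array, failed_qc, tested\}.
#' @export
lookup_candidates <- function(results, candidate_cpgs, manifest, qc_report = NULL) {
  if (!length(candidate_cpgs)) stop("candidate list is empty")
  status <- ifelse(!(candidate_cpgs %in% manifest$probe_id), "absent_from_array",
                   ifelse(candidate_cpgs %in% results$probe_id, "tested",
                          "failed_qc"))
  idx <- match(candidate_cpgs, results$probe_id)
  data.frame(probe_id = candidate_cpgs, status = status,
             effect = ifelse(status == "tested", results$effect[idx], NA_real_),
             p = ifelse(status == "tested", results$p[idx], NA_real_),
             stringsAsFactors = FALSE)
}
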