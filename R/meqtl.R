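#' Chromosome-wide meQTL scan for one CpG
#'
#' Per variant, ordinary least squares of the CpG's M-values on the
#' effect-allele dosage plus covariates (typically methylation PCs), fitted
#' through Frisch-Waugh residualization so the whole chromosome is scanned
#' in one pass; slopes, classical SEs and two-sided t p-values are identical
#' to the full per-variant OLS. Monomorphic variants return NA with a
#' warning.
#'
#' @param mvalues Named numeric vector of M-values for one CpG (names =
#'   sample ids).
#' @param genotypes A [genotype_matrix()] restricted to the CpG's
#'   chromosome (or any variant set to scan).
#' @param covariates Optional samples x q covariate matrix.
#' @return data.frame of class \code{"meqtl_stats"}: variant_id, chrom, pos,
#'   effect_allele, beta, se, t, p, n.
#' @export
scan_meqtl <- function(mvalues, genotypes, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(names(mvalues))) stop("'mvalues' must be named by sample id")
  ids <- intersect(rownames(genotypes$dosage), names(mvalues))
  if (length(ids) < 4) stop("too few samples shared between M-values and genotypes")
  mv <- mvalues[ids]
  g <- genotypes$dosage[ids, , drop = FALSE]
  x0 <- design_with_intercept(length(ids), covariates, ids)
  q0 <- qr(x0)
  if (q0$rank < ncol(x0)) stop("covariate matrix is rank deficient")

  mono <- apply(g, 2, stats::var) == 0
  if (any(mono))
    warning(sum(mono), " monomorphic variant(s) returned NA")
  mr <- qr.resid(q0, mv)
  gr <- qr.resid(q0, g)
  gss <- colSums(gr^2)
  slope <- colSums(gr * mr) / gss
  df <- length(ids) - ncol(x0) - 1
  rss <- pmax(sum(mr^2) - slope^2 * gss, 0)
  se <- sqrt(rss / df / gss)
  tstat <- slope / se
  slope[mono] <- se[mono] <- tstat[mono] <- NA_real_
  v <- genotypes$variants
  out <- data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                    effect_allele = v$effect_allele, beta = slope, se = se,
                    t = tstat, p = 2 * stats::pt(-abs(tstat), df),
                    n = length(ids), row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("meqtl_stats", "data.frame")
  out
}

#' Squared dosage correlation (LD r-squared) between two variants
#'
#' @param genotypes A [genotype_matrix()], or a numeric dosage vector (in
#'   which case \code{v1} must be the second vector).
#' @param v1,v2 Variant ids (or, for the vector interface, \code{v1} is the
#'   second dosage vector and \code{v2} is unused).
#' @return Squared Pearson correlation; invariant to allele flips
#'   (g -> 2 - g).
#' @export
ld_r2 <- function(genotypes, v1, v2 = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    miss <- setdiff(c(v1, v2), colnames(genotypes$dosage))
    if (length(miss)) stop("variant(s) absent: ", paste(miss, collapse = ", "))
    a <- genotypes$dosage[, v1]
    b <- genotypes$dosage[, v2]
  } else {
    a <- genotypes
    b <- v1
  }
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("r-squared undefined for a constant dosage")
  stats::cor(a, b)^2
}

#' Build an independent instrument set by greedy LD pruning
#'
#' Standard clumping semantics: variants with scan p-value below
#' \code{p_threshold} are sorted by ascending p (ties broken
#' deterministically by chromosome, position, then id) and accepted greedily
#' - a variant joins the set only if its in-sample r-squared with every
#' already-accepted variant is below \code{r2_threshold}. An empty set is
#' returned flagged rather than dropped.
#'
#' @param stats A [scan_meqtl()] result.
#' @param genotypes The [genotype_matrix()] the scan was run on.
#' @param cpg Optional CpG id the set instruments.
#' @param p_threshold Inclusion p-value threshold (default 1e-3).
#' @param r2_threshold Pairwise r-squared bound (default 0.2).
#' @return An object of class \code{"instrument_set"}: list(cpg, variants =
#'   retained rows of \code{stats}, params, flag = "ok" or
#'   "no_instruments").
#' @export
build_instrument_set <- function(stats, genotypes, cpg = NULL,
                                 p_threshold = 1e-3, r2_threshold = 0.2) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  miss <- setdiff(stats$variant_id, colnames(genotypes$dosage))
  if (length(miss)) stop("scan variants absent from genotypes: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  qual <- stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  qual <- qual[order(qual$p, qual$chrom, qual$pos, qual$variant_id), , drop = FALSE]
  kept <- character(0)
  for (v in qual$variant_id) {
    ok <- all(vapply(kept, function(k) ld_r2(genotypes, v, k) < r2_threshold, TRUE))
    if (ok) kept <- c(kept, v)
  }
  variants <- qual[match(kept, qual$variant_id), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(cpg = cpg, variants = variants,
                 params = list(p_threshold = p_threshold,
                               r2_threshold = r2_threshold),
                 flag = if (length(kept)) "ok" else "no_instruments"),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("instrument_set", if (!is.null(x$cpg)) paste0("for ", x$cpg) else "",
      sprintf("| %d instrument(s) [%s] (p < %g, r2 < %g)\n",
              nrow(x$variants), x$flag, x$params$p_threshold,
              x$params$r2_threshold))
  if (nrow(x$variants)) print.data.frame(x$variants, digits = 3)
  invisible(x)
}
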