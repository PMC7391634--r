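#' Estimate surrogate variables for unmeasured technical structure
#'
#' Latent-factor discovery is run on the matrix residualized on the
#' protected design - the biological covariates whose signal must not drive
#' factor discovery: the top right singular vectors of the residual matrix
#' give the probe loadings of the latent factors. The surrogate variables
#' themselves are then the projections of the \emph{raw} (column-centered)
#' data onto those loadings, orthonormalized. Estimating the factors from
#' the raw data is essential: a factor that is partially confounded with the
#' protected design by chance must retain that component, otherwise
#' adjusting for the surrogate variables cannot remove the confounding bias
#' it induces (it would only shrink standard errors and worsen the genomic
#' inflation).
#'
#' When \code{k = "auto"} the number of factors is chosen by permutation
#' parallel analysis: each probe's residuals are permuted across samples
#' \code{n_perm} times and a component is kept while its residual singular
#' value exceeds the \code{perm_quantile} permutation quantile of the
#' corresponding order statistic (components kept contiguously from the
#' first). The default quantile is 0.99: the permutation null is conditional
#' on the realized matrix and is anti-conservative for the leading component
#' at 0.95 (pure-noise matrices retain a spurious component in roughly 15%
#' of runs; at 0.99 the rate is a few percent).
#'
#' @param m A [methylation_matrix()].
#' @param protected_design Numeric vector or samples x q matrix of protected
#'   covariates (an intercept is always added).
#' @param k Number of surrogate variables, or \code{"auto"}.
#' @param values Run on \code{"m"} (default) or \code{"beta"} values.
#' @param n_perm Permutations for parallel analysis (default 100).
#' @param perm_quantile Permutation quantile for retention (default 0.99).
#' @param epsilon Clipping bound passed to [beta_to_m()].
#' @return Samples x k matrix of orthonormal surrogate variables (possibly
#'   zero columns) with attributes \code{singular_values} and
#'   \code{thresholds} (when auto-selected).
#' @export
estimate_surrogate_variables <- function(m, protected_design, k = "auto",
                                         values = c("m", "beta"), n_perm = 100,
                                         perm_quantile = 0.99, epsilon = 1e-3) {
  stopifnot(inherits(m, "methylation_matrix"))
  values <- match.arg(values)
  ids <- colnames(m$beta)
  y <- t(if (values == "m") beta_to_m(m$beta, epsilon) else m$beta)
  x <- design_with_intercept(nrow(y), protected_design, ids)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("protected design is rank deficient")
  if (!identical(k, "auto")) {
    if (!is.numeric(k) || k < 0) stop("'k' must be \"auto\" or a non-negative count")
    if (nrow(y) < k + qx$rank + 1)
      stop("too few samples for ", k, " surrogate variables")
  }
  r <- qr.resid(qx, y)
  sv <- svd(r)

  thresholds <- NULL
  if (identical(k, "auto")) {
    nd <- length(sv$d)
    perm_d <- matrix(NA_real_, n_perm, nd)
    for (b in seq_len(n_perm)) {
      rp <- apply(r, 2, sample)
      perm_d[b, ] <- svd(rp, nu = 0, nv = 0)$d
    }
    thresholds <- apply(perm_d, 2, stats::quantile, probs = perm_quantile)
    keep <- sv$d > thresholds
    k <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 0L
  }
  k <- min(k, length(sv$d))
  if (k == 0) {
    out <- matrix(numeric(0), nrow(y), 0, dimnames = list(ids, NULL))
  } else {
    yc <- sweep(y, 2, colMeans(y))
    raw <- yc %*% sv$v[, seq_len(k), drop = FALSE]
    out <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
    dimnames(out) <- list(ids, paste0("SV", seq_len(k)))
  }
  attr(out, "singular_values") <- sv$d
  attr(out, "thresholds") <- thresholds
  out
}

#' Top methylation principal components
#'
#' PCA of the column-centered sample x probe matrix: scores are the top-k
#' left singular vectors scaled by their singular values, with variance
#' explained reported in non-increasing order.
#'
#' @param m A [methylation_matrix()].
#' @param k Number of components, at most \code{min(dim) - 1}.
#' @param values \code{"beta"} (default) or \code{"m"}.
#' @param epsilon Clipping bound passed to [beta_to_m()].
#' @return list(scores = samples x k matrix (columns \code{mePC1, ...}),
#'   var_explained = length-k vector, sdev = all singular values /
#'   sqrt(n - 1)).
#' @export
methylation_pcs <- function(m, k, values = c("beta", "m"), epsilon = 1e-3) {
  stopifnot(inherits(m, "methylation_matrix"))
  values <- match.arg(values)
  y <- t(if (values == "m") beta_to_m(m$beta, epsilon) else m$beta)
  if (k < 1 || k > min(dim(y)) - 1)
    stop("'k' must lie between 1 and min(dim) - 1")
  yc <- sweep(y, 2, colMeans(y))
  sv <- svd(yc, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(colnames(m$beta), paste0("mePC", seq_len(k)))
  list(scores = scores,
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       sdev = sv$d / sqrt(nrow(y) - 1))
}
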