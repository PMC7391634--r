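#' Convert methylation beta values to M-values
#'
#' The M-value is the log2 odds of methylation, \code{M = log2(beta / (1 -
#' beta))}. Betas are clipped into \code{[epsilon, 1 - epsilon]} before the
#' transform so boundary values stay finite; inside the clipping region the
#' transform is exactly invertible by [m_to_beta()].
#'
#' @param beta Numeric vector or matrix of methylation fractions in
#'   \code{[0, 1]}. \code{NA}s are propagated.
#' @param epsilon Clipping bound in \code{(0, 0.5)}; default \code{1e-3}.
#' @return M-values with the same shape as \code{beta}.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5)
    stop("'epsilon' must be a single value in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie within [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b) - log2(1 - b)
  attributes(m) <- attributes(beta)
  m
}

#' Convert M-values back to methylation beta values
#'
#' Inverse of [beta_to_m()]: \code{beta = 2^M / (1 + 2^M)}, computed through
#' the logistic CDF for numerical stability at large \code{|M|}.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta values in \code{(0, 1)} with the same shape as \code{m}.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("'m' must be numeric")
  b <- stats::plogis(log(2) * m)
  attributes(b) <- attributes(m)
  b
}

## shared internal helpers ----------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

## percentage as printed in descriptive tables: one decimal by default
percent_of <- function(n, total, digits = 1) round(100 * n / total, digits)

## bind an intercept and optional covariate matrix into a design matrix
design_with_intercept <- function(n, covariates = NULL, ids = NULL) {
  x <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (is.null(covariates)) return(x)
  covariates <- as.matrix(covariates)
  if (!is.null(ids) && !is.null(rownames(covariates))) {
    missing <- setdiff(ids, rownames(covariates))
    if (length(missing))
      stop("covariates missing for samples: ", paste(utils::head(missing, 5), collapse = ", "))
    covariates <- covariates[ids, , drop = FALSE]
  }
  if (nrow(covariates) != n) stop("covariate rows do not match the number of samples")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
  cbind(x, covariates)
}
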