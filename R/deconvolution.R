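#' Reference-based cell-type deconvolution by non-negative least squares
#'
#' For each sample, regresses its beta values at the shared marker probes on
#' the reference cell-type profiles under a non-negativity constraint
#' (Lawson-Hanson NNLS via \code{pracma::lsqnonneg}), then renormalizes the
#' coefficients to sum to one. The \code{"huber"} method iteratively
#' reweights the marker probes with Huber weights before each NNLS solve,
#' down-weighting outlying markers.
#'
#' @param m A [methylation_matrix()].
#' @param reference Markers x cell-types beta profile matrix (marker probe
#'   ids as rownames), e.g. [default_cell_reference()].
#' @param method \code{"nnls"} (default) or \code{"huber"}.
#' @param huber_k Huber tuning constant in residual-MAD units (default
#'   1.345).
#' @param max_iter Maximum reweighting iterations for \code{"huber"}.
#' @return Samples x cell-types matrix of fractions; each row is
#'   non-negative and sums to 1.
#' @export
estimate_cell_fractions <- function(m, reference, method = c("nnls", "huber"),
                                    huber_k = 1.345, max_iter = 20) {
  stopifnot(inherits(m, "methylation_matrix"))
  method <- match.arg(method)
  reference <- as.matrix(reference)
  if (any(reference < 0 | reference > 1)) stop("reference profiles must lie in [0, 1]")
  shared <- intersect(rownames(reference), rownames(m$beta))
  if (!length(shared)) stop("no marker probes shared between matrix and reference")
  a <- reference[shared, , drop = FALSE]
  b <- m$beta[shared, , drop = FALSE]

  solve_one <- function(y) {
    ok <- !is.na(y)
    x <- pracma::lsqnonneg(a[ok, , drop = FALSE], y[ok])$x
    if (method == "huber") {
      w <- rep(1, sum(ok))
      for (it in seq_len(max_iter)) {
        r <- y[ok] - a[ok, , drop = FALSE] %*% x
        s <- stats::mad(r)
        if (s < 1e-10) break
        w_new <- pmin(1, huber_k * s / pmax(abs(r), 1e-12))
        if (max(abs(w_new - w)) < 1e-8) break
        w <- w_new
        x <- pracma::lsqnonneg(sqrt(w) * a[ok, , drop = FALSE], sqrt(w) * y[ok])$x
      }
    }
    x
  }
  coefs <- t(apply(b, 2, solve_one))
  tot <- rowSums(coefs)
  degenerate <- tot <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " sample(s) had an all-zero NNLS fit; ",
            "fractions set uniform")
    coefs[degenerate, ] <- 1
    tot[degenerate] <- ncol(coefs)
  }
  fractions <- coefs / tot
  dimnames(fractions) <- list(colnames(b), colnames(a))
  fractions
}

#' Compare estimated cell fractions between two groups
#'
#' Per cell type, a two-sample location test of the fractions between the
#' two groups: Wilcoxon rank-sum by default (ties handled by the normal
#' approximation), or Welch's t-test.
#'
#' @param fractions Samples x cell-types matrix from
#'   [estimate_cell_fractions()].
#' @param groups Factor-like vector of length \code{nrow(fractions)} with
#'   exactly two levels.
#' @param method \code{"wilcoxon"} (default) or \code{"t"}.
#' @return data.frame(cell_type, statistic, p).
#' @export
compare_cell_fractions <- function(fractions, groups, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs at least two samples")
  if (length(groups) != nrow(fractions)) stop("'groups' must match rows of 'fractions'")
  res <- lapply(colnames(fractions), function(ct) {
    x <- fractions[groups == levels(groups)[1], ct]
    y <- fractions[groups == levels(groups)[2], ct]
    ht <- tryCatch(
      if (method == "wilcoxon")
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      else stats::t.test(x, y),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    ## fully tied data leave the test statistic degenerate: report the
    ## maximal attainable p
    p <- if (is.na(ht$p.value)) 1 else ht$p.value
    data.frame(cell_type = ct, statistic = unname(ht$statistic),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
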