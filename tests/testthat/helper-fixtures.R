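# Shared fixture builders: everything is generated in code at test time.

toy_manifest <- function(probe_ids, chrom = "1", pos = NULL,
                         probe_class = "cg", snp_flag = FALSE) {
  data.frame(probe_id = probe_ids, chrom = chrom,
             pos = pos %||% seq_along(probe_ids) * 1000L,
             probe_class = rep_len(probe_class, length(probe_ids)),
             snp_flag = rep_len(snp_flag, length(probe_ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random methylation matrix whose betas come from Gaussian M-values
toy_methylation <- function(n_probes, n_samples, m_mean = 0, m_sd = 0.5,
                            seed = NULL, chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n_probes * n_samples, m_mean, m_sd), n_probes, n_samples)
  beta <- m_to_beta(m)
  dimnames(beta) <- list(sprintf("cg%06d", seq_len(n_probes)),
                         sprintf("S%03d", seq_len(n_samples)))
  methylation_matrix(beta, toy_manifest(rownames(beta), chrom = chrom))
}

toy_phenotype <- function(y, ids = NULL) {
  ids <- ids %||% sprintf("S%03d", seq_along(y))
  data.frame(sample_id = ids, hypospadias = y, chordee = NA_integer_,
             severity = NA_character_,
             subject_age_months = 10, tissue_age_months = 12,
             stringsAsFactors = FALSE)
}

## a null simulation config (no planted effects, no batch)
null_sim_config <- function(n_cases = 45, n_controls = 46, n_cpgs = 200,
                            seed = 1, ...) {
  simulation_config(
    n_cases = n_cases, n_controls = n_controls,
    n_chordee = min(21, n_cases), n_severe = min(9, n_cases),
    n_cpgs = n_cpgs,
    meqtl_effects = data.frame(cpg = character(0), variant = character(0),
                               effect = numeric(0)),
    causal_cpg_effects = data.frame(cpg = character(0), design = character(0),
                                    effect = numeric(0)),
    batch_sd = 0, seed = seed, ...)
}

## quadratic-time Benjamini-Hochberg reference used as an oracle
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        min(1, m * p[j] / rank_j)
      } else Inf
    }, 0)
    min(cand)
  }, 0)
}

## definitional stepwise pruning oracle: accept qualifying variants in
## (p, chrom, pos, id) order unless r2 with an accepted one reaches the bound
prune_oracle <- function(stats, dosage, p_threshold, r2_threshold) {
  qual <- stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  qual <- qual[order(qual$p, qual$chrom, qual$pos, qual$variant_id), , drop = FALSE]
  kept <- character(0)
  for (v in qual$variant_id) {
    conflict <- FALSE
    for (k in kept)
      if (stats::cor(dosage[, v], dosage[, k])^2 >= r2_threshold) conflict <- TRUE
    if (!conflict) kept <- c(kept, v)
  }
  kept
}
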