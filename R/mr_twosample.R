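#' Map genes in cis to a CpG position
#'
#' Returns every gene whose interval overlaps the window of
#' \code{window} bp up- and downstream of the CpG (inclusive bounds,
#' 1-based coordinates) on the same chromosome. \code{mode = "tss"}
#' restricts to genes whose start lies within the window instead.
#'
#' @param cpg_chrom,cpg_pos Chromosome and 1-based position of the CpG.
#' @param genes Annotation data.frame with columns \code{gene},
#'   \code{chrom}, \code{start}, \code{end}.
#' @param window Half-width of the cis window in bp (default 500000).
#' @param mode \code{"interval"} (default) or \code{"tss"}.
#' @return The overlapping rows of \code{genes} (empty, with a warning, for
#'   a chromosome absent from the annotation).
#' @export
map_cis_genes <- function(cpg_chrom, cpg_pos, genes, window = 5e5,
                          mode = c("interval", "tss")) {
  mode <- match.arg(mode)
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(genes)))
    stop("gene annotation needs columns: ", paste(req, collapse = ", "))
  if (!(cpg_chrom %in% genes$chrom)) {
    warning("chromosome ", cpg_chrom, " absent from the gene annotation")
    return(genes[0, , drop = FALSE])
  }
  lo <- cpg_pos - window
  hi <- cpg_pos + window
  sel <- genes$chrom == cpg_chrom &
    (if (mode == "interval") genes$start <= hi & genes$end >= lo
     else genes$start >= lo & genes$start <= hi)
  out <- genes[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

pal_pairs <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect allele: records already
#' on the same orientation are kept; records whose alleles are swapped have
#' the outcome beta negated and alleles swapped (\code{flipped});
#' palindromic variants (A/T, C/G) are dropped by default since strand
#' cannot be resolved without allele frequencies; allele pairs that match
#' neither orientation are dropped as mismatches. Applying the function to
#' its own output changes nothing.
#'
#' @param exposure,outcome Summary-statistic data.frames with columns
#'   \code{variant_id}, \code{effect_allele}, \code{other_allele},
#'   \code{beta}, \code{se} (exposure rows may also carry \code{gene},
#'   \code{tissue}, \code{p}).
#' @param drop_palindromic Drop palindromic variants (default TRUE).
#' @return data.frame with the exposure columns, aligned
#'   \code{beta_outcome}/\code{se_outcome}, and an \code{action} column in
#'   \{kept, flipped, dropped_palindromic, dropped_mismatch\}. Dropped rows
#'   carry NA outcome effects.
#' @export
harmonize_summary_stats <- function(exposure, outcome, drop_palindromic = TRUE) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) stop("no shared variants between exposure and outcome")
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  aligned <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  pal <- paste(ex$effect_allele, ex$other_allele, sep = "/") %in% pal_pairs
  action <- ifelse(drop_palindromic & pal, "dropped_palindromic",
                   ifelse(aligned, "kept",
                          ifelse(swapped, "flipped", "dropped_mismatch")))
  beta_out <- ifelse(action == "kept", ou$beta,
                     ifelse(action == "flipped", -ou$beta, NA_real_))
  se_out <- ifelse(action %in% c("kept", "flipped"), ou$se, NA_real_)
  out <- ex
  out$beta_outcome <- beta_out
  out$se_outcome <- se_out
  out$action <- action
  rownames(out) <- NULL
  out
}

#' Single-instrument Wald-ratio Mendelian randomization
#'
#' The Wald ratio: causal estimate \code{b_y / b_x} with first-order
#' delta-method standard error \code{se_y / |b_x|} (the second-order option
#' adds the exposure-uncertainty term), Wald z statistic and two-sided
#' normal p-value. Vectorized over records.
#'
#' @param b_exposure,se_exposure Instrument effect and SE on the exposure
#'   (gene expression); \code{b_exposure} must be nonzero.
#' @param b_outcome,se_outcome Instrument effect and SE on the outcome.
#' @param second_order Include the exposure SE in the delta-method SE.
#' @return data.frame(estimate, se, z, p).
#' @export
wald_ratio_mr <- function(b_exposure, se_exposure, b_outcome, se_outcome,
                          second_order = FALSE) {
  if (any(b_exposure == 0, na.rm = TRUE))
    stop("Wald ratio undefined for a zero exposure effect")
  est <- b_outcome / b_exposure
  se <- if (second_order)
    sqrt(se_outcome^2 / b_exposure^2 + b_outcome^2 * se_exposure^2 / b_exposure^4)
  else se_outcome / abs(b_exposure)
  z <- est / se
  data.frame(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Wald-ratio MR over a harmonized summary-statistic table
#'
#' Applies [wald_ratio_mr()] to every non-dropped record of a
#' [harmonize_summary_stats()] result, one result per (gene, tissue) record
#' as is conventional for per-tissue eQTL instruments.
#'
#' @param harmonized Output of [harmonize_summary_stats()].
#' @param alpha Significance threshold for the flag column (default 0.05);
#'   no rows are dropped.
#' @param second_order Passed to [wald_ratio_mr()].
#' @return data.frame(gene, tissue, variant_id, estimate, se, z, p,
#'   significant, action) including the dropped records with NA estimates.
#' @export
run_wald_mr <- function(harmonized, alpha = 0.05, second_order = FALSE) {
  usable <- harmonized$action %in% c("kept", "flipped")
  est <- data.frame(estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_)[rep(1, nrow(harmonized)), , drop = FALSE]
  if (any(usable))
    est[usable, ] <- wald_ratio_mr(harmonized$beta[usable],
                                   harmonized$se[usable],
                                   harmonized$beta_outcome[usable],
                                   harmonized$se_outcome[usable],
                                   second_order = second_order)
  out <- data.frame(gene = harmonized$gene %||% NA_character_,
                    tissue = harmonized$tissue %||% NA_character_,
                    variant_id = harmonized$variant_id,
                    est, significant = !is.na(est$p) & est$p < alpha,
                    action = harmonized$action,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
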