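#' Cross-reference suggestive CpGs with GWAS index variants
#'
#' Pairs each CpG with every index variant on the same chromosome within
#' \code{window} bp up- or downstream (inclusive bounds), the criterion used
#' to ask whether methylation could mediate a published genetic
#' association.
#'
#' @param cpgs data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (e.g. a [select_suggestive()] table).
#' @param index data.frame of GWAS index variants with columns
#'   \code{variant_id}, \code{chrom}, \code{pos}.
#' @param window Half-width in bp (default 500000).
#' @return data.frame(probe_id, variant_id, chrom, cpg_pos, index_pos,
#'   distance).
#' @export
overlap_gwas_regions <- function(cpgs, index, window = 5e5) {
  pairs <- merge(cpgs[, c("probe_id", "chrom", "pos")],
                 index[, c("variant_id", "chrom", "pos")],
                 by = "chrom", suffixes = c("_cpg", "_index"))
  pairs <- pairs[abs(pairs$pos_cpg - pairs$pos_index) <= window, , drop = FALSE]
  out <- data.frame(probe_id = pairs$probe_id, variant_id = pairs$variant_id,
                    chrom = pairs$chrom, cpg_pos = pairs$pos_cpg,
                    index_pos = pairs$pos_index,
                    distance = abs(pairs$pos_cpg - pairs$pos_index),
                    stringsAsFactors = FALSE)
  out[order(out$probe_id, out$distance), , drop = FALSE]
}

#' Linkage between meQTL instruments and a GWAS index variant
#'
#' Computes the reference-panel r-squared between each instrument and the
#' index variant and delivers a mediation verdict: \code{"linked"} when the
#' maximum r-squared reaches \code{r2_threshold}, \code{"independent"}
#' otherwise, \code{"untestable"} when the index variant is absent from the
#' panel. When study genotypes and the CpG's M-values are supplied, the
#' direct index-variant meQTL p-value is reported as well.
#'
#' @param instruments An [build_instrument_set()] result.
#' @param index_variant Index variant id.
#' @param panel Reference-panel [genotype_matrix()] containing the
#'   instruments and (ideally) the index variant.
#' @param r2_threshold Linkage threshold (default 0.2, matching the
#'   instrument-pruning bound).
#' @param study_genotypes,study_mvalues Optional study [genotype_matrix()]
#'   and named M-value vector for the direct index-variant meQTL test.
#' @return list(r2 = named per-instrument r-squared vector, max_r2, verdict,
#'   index_meqtl_p).
#' @export
instrument_index_ld <- function(instruments, index_variant, panel,
                                r2_threshold = 0.2, study_genotypes = NULL,
                                study_mvalues = NULL) {
  stopifnot(inherits(instruments, "instrument_set"),
            inherits(panel, "genotype_matrix"))
  ivs <- instruments$variants$variant_id
  direct_p <- NA_real_
  if (!is.null(study_genotypes) && !is.null(study_mvalues) &&
      index_variant %in% colnames(study_genotypes$dosage)) {
    sc <- scan_meqtl(study_mvalues, study_genotypes[, index_variant])
    direct_p <- sc$p[1]
  }
  if (!(index_variant %in% colnames(panel$dosage)))
    return(list(r2 = stats::setNames(rep(NA_real_, length(ivs)), ivs),
                max_r2 = NA_real_, verdict = "untestable",
                index_meqtl_p = direct_p))
  miss <- setdiff(ivs, colnames(panel$dosage))
  if (length(miss)) stop("instrument(s) absent from the panel: ",
                         paste(miss, collapse = ", "))
  r2 <- vapply(ivs, function(v) ld_r2(panel, v, index_variant), 0)
  max_r2 <- if (length(r2)) max(r2) else NA_real_
  verdict <- if (!length(r2)) "untestable"
             else if (max_r2 >= r2_threshold) "linked" else "independent"
  list(r2 = r2, max_r2 = max_r2, verdict = verdict, index_meqtl_p = direct_p)
}
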