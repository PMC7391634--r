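#' Published per-CpG EWAS / MR summary table
#'
#' The printed summary of the 25 suggestive CpGs from the hypospadias
#' case-control and case-only scans this package models: per-design group
#' mean betas (three printed decimals), the printed comparison-minus-case
#' delta beta, EWAS p/q-values, the number of independent meQTL instruments,
#' and the 2SLS MR p-value. Positions are genome build 37. Used by the
#' worked examples to check the delta-beta arithmetic against printed
#' values.
#'
#' @return data.frame with one row per (design, CpG).
#' @export
published_ewas_table <- function() {
  path <- system.file("extdata", "published_ewas_mr_summary.tsv",
                      package = "methylmr", mustWork = TRUE)
  read_tsv_commented(path)
}
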