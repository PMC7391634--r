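## All tables are written as TSV with '#'-prefixed provenance comment lines,
## 1-based inclusive coordinates, and an explicit effect-allele column in
## every genetic table.

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  ## chromosome labels are names, not numbers
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  out
}

#' Write / read a methylation matrix as TSV
#'
#' Two files: the beta matrix (rows = probes, first column \code{probe_id},
#' remaining columns = sample ids) and the probe manifest.
#'
#' @param m A [methylation_matrix()].
#' @param beta_path,manifest_path Output paths.
#' @return (write) the paths, invisibly; (read) a [methylation_matrix()].
#' @export
write_methylation_tsv <- function(m, beta_path, manifest_path) {
  stopifnot(inherits(m, "methylation_matrix"))
  beta <- data.frame(probe_id = rownames(m$beta), m$beta, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv_commented(beta, beta_path,
                      c("methylation beta values; rows = probes, columns = samples"))
  write_tsv_commented(m$manifest, manifest_path,
                      c("probe manifest; pos is 1-based"))
  invisible(c(beta_path, manifest_path))
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(beta_path, manifest_path) {
  b <- read_tsv_commented(beta_path)
  beta <- as.matrix(b[, -1, drop = FALSE])
  rownames(beta) <- b$probe_id
  methylation_matrix(beta, read_tsv_commented(manifest_path))
}

#' Write / read genotype dosages as TSV
#'
#' Rows = variants with their metadata columns, then one dosage column per
#' sample.
#'
#' @param g A [genotype_matrix()].
#' @param path File path.
#' @return (write) the path, invisibly; (read) a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "effect_allele")
  df <- cbind(g$variants[, meta_cols],
              as.data.frame(t(g$dosage), check.names = FALSE))
  write_tsv_commented(df, path, "genotype dosages in [0,2]; pos is 1-based")
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv_commented(path)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "effect_allele")
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dos) <- df$variant_id
  genotype_matrix(dos, df[, meta_cols])
}

#' Write a genotype matrix as a plain-text dosage VCF
#'
#' Minimal VCFv4.2 with a \code{DS} (dosage) FORMAT field, uncompressed.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (".vcf").
#' @return The path, invisibly.
#' @export
write_dosage_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g$dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i], ".",
            "PASS", ".", "DS", format(g$dosage[, i], trim = TRUE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the \code{DS} FORMAT field when present and falls back to hard-call
#' allele counts from \code{GT} otherwise. Requires the \pkg{vcfR} package.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()]; the ALT allele is the effect allele.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(ds) <- ids
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, effect_allele = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants)
}

#' Write / read a phenotype table as TSV
#' @param phenotype Phenotype data.frame.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  write_tsv_commented(as.data.frame(phenotype), path,
                      "phenotype table; chordee/severity are NA for controls")
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  out <- read_tsv_commented(path)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write / read summary statistics as TSV
#' @param stats Summary-statistic data.frame.
#' @param path File path.
#' @export
write_summary_stats_tsv <- function(stats, path) {
  write_tsv_commented(stats, path,
                      "summary statistics; beta is per effect_allele dose")
}

#' @rdname write_summary_stats_tsv
#' @export
read_summary_stats_tsv <- function(path) read_tsv_commented(path)
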