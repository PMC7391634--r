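#' Construct a methylation matrix with its probe manifest
#'
#' The central methylation container: a probes x samples matrix of beta
#' values linked to a probe manifest (chromosome, 1-based position, probe
#' class, SNP flag) and, optionally, per-probe/per-sample detection p-values
#' and bead-failure flags used by the QC filters.
#'
#' @param beta Numeric probes x samples matrix with probe ids as rownames and
#'   sample ids as colnames; values in \code{[0, 1]} or \code{NA}.
#' @param manifest data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (1-based), \code{probe_class} (one of \code{"cg"},
#'   \code{"ch"}, \code{"rs"}) and logical \code{snp_flag}. Rows must match
#'   the probes of \code{beta} (any order; matched by id).
#' @param detection_p Optional probes x samples matrix of detection p-values.
#' @param bead_fail Optional probes x samples logical matrix flagging probes
#'   measured with too few beads in a sample.
#' @return An object of class \code{"methylation_matrix"}.
#' @export
methylation_matrix <- function(beta, manifest, detection_p = NULL, bead_fail = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' needs probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids")
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values must lie within [0, 1]")
  req <- c("probe_id", "chrom", "pos", "probe_class", "snp_flag")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  if (!setequal(manifest$probe_id, rownames(beta)))
    stop("manifest probes do not match the beta matrix")
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  rownames(manifest) <- NULL
  check_aligned <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (!identical(dim(x), dim(beta))) stop("'", what, "' must match dim(beta)")
    dimnames(x) <- dimnames(beta)
    x
  }
  structure(list(beta = beta, manifest = manifest,
                 detection_p = check_aligned(detection_p, "detection_p"),
                 bead_fail = check_aligned(bead_fail, "bead_fail")),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  cat("  probe classes:",
      paste(names(table(x$manifest$probe_class)), table(x$manifest$probe_class),
            sep = "=", collapse = ", "), "\n")
  cat("  detection p-values:", if (is.null(x$detection_p)) "absent" else "present",
      "| bead flags:", if (is.null(x$bead_fail)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$beta)

## subset a methylation matrix by probe and/or sample ids (internal)
subset_methylation <- function(m, probes = NULL, samples = NULL) {
  probes <- probes %||% rownames(m$beta)
  samples <- samples %||% colnames(m$beta)
  take <- function(x) if (is.null(x)) NULL else x[probes, samples, drop = FALSE]
  methylation_matrix(m$beta[probes, samples, drop = FALSE],
                     m$manifest[match(probes, m$manifest$probe_id), , drop = FALSE],
                     detection_p = take(m$detection_p),
                     bead_fail = take(m$bead_fail))
}

#' Construct a genotype dosage matrix
#'
#' @param dosage Numeric samples x variants matrix of expected alternate
#'   allele counts in \code{[0, 2]}; sample ids as rownames, variant ids as
#'   colnames.
#' @param variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}, \code{effect_allele}.
#' @return An object of class \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("'dosage' needs sample ids as rownames and variant ids as colnames")
  if (anyDuplicated(colnames(dosage))) stop("duplicate variant ids")
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) stop("dosages must lie within [0, 2]")
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "effect_allele")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (!setequal(variants$variant_id, colnames(dosage)))
    stop("variant table does not match the dosage matrix")
  variants <- variants[match(colnames(dosage), variants$variant_id), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants",
      "on chromosome(s)", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Sample ids or indices.
#' @param j Variant ids or indices.
#' @param ... Ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  d <- x$dosage[i, j, drop = FALSE]
  genotype_matrix(d, x$variants[match(colnames(d), x$variants$variant_id), , drop = FALSE])
}
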