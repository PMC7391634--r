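#' Filter samples on detection-p failure rate and sex-mismatch flags
#'
#' A sample is removed when the fraction of its probes failing detection
#' (detection p-value above \code{detection_threshold}) exceeds
#' \code{max_fail_fraction}, or when it carries an externally supplied
#' sex-mismatch flag (sex prediction itself happens upstream of this
#' package). Matrices without detection p-values pass the detection filter
#' unchanged.
#'
#' @param m A [methylation_matrix()].
#' @param detection_threshold Per-probe detection p-value cutoff (default
#'   0.01).
#' @param max_fail_fraction Maximum tolerated fraction of failing probes per
#'   sample (default 0.05).
#' @param sex_mismatch Character vector of sample ids flagged as
#'   sex-mismatched.
#' @return list(matrix = filtered [methylation_matrix()], report = QC report
#'   list with \code{samples_removed} (id, reason) and before/after counts).
#' @export
filter_samples <- function(m, detection_threshold = 0.01,
                           max_fail_fraction = 0.05, sex_mismatch = character()) {
  stopifnot(inherits(m, "methylation_matrix"))
  ids <- colnames(m$beta)
  removed <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(m$detection_p)) {
    fail_frac <- colMeans(m$detection_p > detection_threshold, na.rm = TRUE)
    bad <- ids[fail_frac > max_fail_fraction]
    if (length(bad))
      removed <- rbind(removed, data.frame(id = bad, reason = "detection",
                                           stringsAsFactors = FALSE))
  }
  mism <- setdiff(intersect(sex_mismatch, ids), removed$id)
  if (length(mism))
    removed <- rbind(removed, data.frame(id = mism, reason = "sex_mismatch",
                                         stringsAsFactors = FALSE))
  keep <- setdiff(ids, removed$id)
  if (!length(keep)) stop("sample QC removed every sample")
  out <- subset_methylation(m, samples = keep)
  list(matrix = out,
       report = list(samples_removed = removed,
                     n_samples = c(before = length(ids), after = length(keep)),
                     n_probes = c(before = nrow(m$beta), after = nrow(m$beta))))
}

#' Filter probes on bead failure, probe class, SNP flags and detection
#'
#' Removes, in order of reason precedence: probes whose detection p-value
#' exceeds \code{detection_threshold} in at least
#' \code{detection_sample_fraction} of samples; probes flagged bead-failed
#' (fewer than 3 beads) in at least \code{bead_fail_fraction_threshold} of
#' samples; non-CpG probes (class \code{ch} or \code{rs}); and
#' SNP-associated probes. Filtering is idempotent.
#'
#' @param m A [methylation_matrix()].
#' @param detection_threshold Detection p-value cutoff (default 0.01).
#' @param detection_sample_fraction Failing-sample fraction at or above
#'   which a probe is removed (default 0.05).
#' @param bead_fail_fraction_threshold Bead-failed sample fraction at or
#'   above which a probe is removed (default 0.05).
#' @return list(matrix, report) as in [filter_samples()], with
#'   \code{probes_removed} reasons in \{detection, beads, non-CpG,
#'   SNP-associated\}.
#' @export
filter_probes <- function(m, detection_threshold = 0.01,
                          detection_sample_fraction = 0.05,
                          bead_fail_fraction_threshold = 0.05) {
  stopifnot(inherits(m, "methylation_matrix"))
  probes <- rownames(m$beta)
  reason <- rep(NA_character_, length(probes))
  if (!is.null(m$detection_p)) {
    det <- rowMeans(m$detection_p > detection_threshold, na.rm = TRUE)
    reason[is.na(reason) & det >= detection_sample_fraction] <- "detection"
  }
  if (!is.null(m$bead_fail)) {
    bead <- rowMeans(m$bead_fail, na.rm = TRUE)
    reason[is.na(reason) & bead >= bead_fail_fraction_threshold] <- "beads"
  }
  reason[is.na(reason) & m$manifest$probe_class != "cg"] <- "non-CpG"
  reason[is.na(reason) & m$manifest$snp_flag] <- "SNP-associated"

  keep <- probes[is.na(reason)]
  if (!length(keep)) stop("probe QC removed every probe")
  removed <- data.frame(id = probes[!is.na(reason)],
                        reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  out <- subset_methylation(m, probes = keep)
  list(matrix = out,
       report = list(probes_removed = removed,
                     n_probes = c(before = length(probes), after = length(keep)),
                     n_samples = c(before = ncol(m$beta), after = ncol(m$beta))))
}

#' Run the full QC sequence (samples, then probes)
#'
#' @inheritParams filter_samples
#' @inheritParams filter_probes
#' @return list(matrix, report) with the merged sample and probe removal
#'   tables.
#' @export
run_qc <- function(m, detection_threshold = 0.01, max_fail_fraction = 0.05,
                   sex_mismatch = character(), detection_sample_fraction = 0.05,
                   bead_fail_fraction_threshold = 0.05) {
  s <- filter_samples(m, detection_threshold, max_fail_fraction, sex_mismatch)
  p <- filter_probes(s$matrix, detection_threshold, detection_sample_fraction,
                     bead_fail_fraction_threshold)
  list(matrix = p$matrix,
       report = list(samples_removed = s$report$samples_removed,
                     probes_removed = p$report$probes_removed,
                     n_samples = s$report$n_samples,
                     n_probes = p$report$n_probes))
}
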