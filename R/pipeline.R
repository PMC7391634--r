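#' Configuration for the full analysis pipeline
#'
#' Bundles the simulator configuration with every stage-level parameter of
#' the pipeline. Can also be populated from a YAML file via
#' [read_pipeline_config()].
#'
#' @param sim A [simulation_config()] for the synthetic study.
#' @param n_mepcs Number of methylation PCs computed as candidate
#'   covariates.
#' @param sv_n_perm Permutations for surrogate-variable parallel analysis.
#' @param meqtl_p,meqtl_r2 Instrument-set thresholds (defaults 1e-3 / 0.2).
#' @param cis_window Cis window in bp for gene mapping and GWAS-region
#'   overlap (default 500000).
#' @param fdr_case_control,fdr_case_only Suggestive FDR thresholds.
#' @param panel_n Reference-panel sample size for index-variant LD.
#' @param genes_per_cpg Synthetic cis genes generated per suggestive CpG for
#'   the two-sample MR stage.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = simulation_config(), n_mepcs = 5,
                            sv_n_perm = 100, meqtl_p = 1e-3, meqtl_r2 = 0.2,
                            cis_window = 5e5, fdr_case_control = 0.20,
                            fdr_case_only = 0.15, panel_n = 200,
                            genes_per_cpg = 6) {
  stopifnot(inherits(sim, "simulation_config"), n_mepcs >= 1, panel_n >= 10)
  structure(list(sim = sim, n_mepcs = n_mepcs, sv_n_perm = sv_n_perm,
                 meqtl_p = meqtl_p, meqtl_r2 = meqtl_r2,
                 cis_window = cis_window, fdr_case_control = fdr_case_control,
                 fdr_case_only = fdr_case_only, panel_n = panel_n,
                 genes_per_cpg = genes_per_cpg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; a \code{sim} block
#' overrides [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  args <- raw
  args$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, args)
}

## Candidate covariate sets for inflation-driven tuning within one design.
## The design-protected surrogate variables play the latent-structure role
## here; global methylation PCs are reserved for the meQTL stage because in
## a scaled-down methylome they carry a non-negligible outcome-proxy
## component (see the methods vignette) - users scanning a full-size
## methylome can pass their own candidate list to tune_covariates().
candidate_covariate_sets <- function(svs, fractions, phenotype, ids) {
  ages <- as.matrix(phenotype[match(ids, phenotype$sample_id),
                              c("subject_age_months", "tissue_age_months")])
  rownames(ages) <- ids
  ## drop one simplex column so fractions are not collinear with the intercept
  frac <- fractions[ids, -1, drop = FALSE]
  sets <- list(none = NULL)
  if (ncol(svs) > 0) {
    sets$sv <- svs
    sets$sv_cells_ages <- cbind(svs, frac, ages)
  } else {
    sets$cells_ages <- cbind(frac, ages)
  }
  sets
}

## deterministic synthetic cis-gene annotation around suggestive CpGs
synthetic_gene_annotation <- function(suggestive, window, genes_per_cpg) {
  if (!nrow(suggestive)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      probe_id = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(suggestive)), function(i) {
    offs <- round(seq(-0.8, 0.8, length.out = genes_per_cpg) * window)
    start <- pmax(suggestive$pos[i] + offs, 1)
    data.frame(gene = sprintf("GENE_%s_%d", suggestive$probe_id[i],
                              seq_len(genes_per_cpg)),
               chrom = suggestive$chrom[i], start = as.integer(start),
               end = as.integer(start + 50000L),
               probe_id = suggestive$probe_id[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulate -> QC -> cell fractions + latent covariates -> three EWAS with
#' inflation-driven covariate tuning -> suggestive-set selection ->
#' chromosome-wide meQTL scans and greedy instrument pruning -> one-sample
#' 2SLS MR per suggestive CpG -> synthetic cis-gene two-sample Wald MR ->
#' GWAS-region overlap with reference-panel LD. Every stage's table is
#' written to \code{out_dir} as a '#'-annotated TSV together with a
#' machine-readable run log; the consolidated per-CpG table joins the EWAS,
#' instrument-count and 2SLS columns.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing.
#' @param seed Integer seed governing all randomness in the run.
#' @return (invisibly) list of class \code{"methylmr_pipeline"} with all
#'   stage objects and the consolidated table.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  config$sim$seed <- as.integer(seed)

  ## 1. synthetic study
  study <- simulate_study(config$sim)

  ## 2. QC
  qc <- run_qc(study$methylation)
  m <- qc$matrix

  ## 3. cell fractions and latent covariates
  reference <- default_cell_reference()
  fractions <- estimate_cell_fractions(m, reference)
  mepcs <- methylation_pcs(m, k = config$n_mepcs)$scores

  ## 4. three EWAS with covariate tuning
  designs <- list(
    ewas_design("hypospadias_case_control", config$fdr_case_control),
    ewas_design("chordee_case_only", config$fdr_case_only),
    ewas_design("severity_case_only", config$fdr_case_only))
  tuning <- list()
  results <- list()
  for (d in designs) {
    y <- design_response(study$phenotype, d)
    ids <- intersect(colnames(m$beta), names(y))
    msub <- subset_methylation(m, samples = ids)
    svs <- estimate_surrogate_variables(msub, protected_design = y[ids],
                                        n_perm = config$sv_n_perm)
    sets <- candidate_covariate_sets(svs, fractions, study$phenotype, ids)
    tuned <- tune_covariates(msub, study$phenotype, d, sets)
    tuning[[d$name]] <- tuned
    results[[d$name]] <- tuned$result
  }

  ## 5. suggestive CpGs
  suggestive <- select_suggestive(results)

  ## 6-7. instruments and one-sample 2SLS MR per suggestive CpG
  mvals_all <- beta_to_m(m$beta)
  mr_rows <- list()
  instruments <- list()
  meqtl_scans <- list()
  for (i in seq_len(nrow(suggestive))) {
    cpg <- suggestive$probe_id[i]
    dsg <- suggestive$design[i]
    chrom <- suggestive$chrom[i]
    on_chrom <- study$genotypes$variants$variant_id[
      study$genotypes$variants$chrom == chrom]
    row <- data.frame(probe_id = cpg, design = dsg, n_meqtls = 0L,
                      mr_estimate = NA_real_, mr_se = NA_real_,
                      mr_p = NA_real_, first_stage_F = NA_real_,
                      mr_note = "no_variants_on_chromosome",
                      stringsAsFactors = FALSE)
    if (length(on_chrom)) {
      g_chrom <- study$genotypes[, on_chrom]
      mv <- mvals_all[cpg, ]
      scan <- scan_meqtl(mv, g_chrom, covariates = mepcs)
      meqtl_scans[[paste(dsg, cpg)]] <- scan
      iv <- build_instrument_set(scan, g_chrom, cpg = cpg,
                                 p_threshold = config$meqtl_p,
                                 r2_threshold = config$meqtl_r2)
      instruments[[paste(dsg, cpg)]] <- iv
      row$n_meqtls <- nrow(iv$variants)
      if (iv$flag == "ok") {
        y <- design_response(study$phenotype, ewas_design(dsg))
        ids <- intersect(names(mv), names(y))
        fit <- tryCatch(
          fit_2sls(mv[ids], y[ids],
                   g_chrom$dosage[ids, iv$variants$variant_id, drop = FALSE]),
          error = function(e) e)
        if (inherits(fit, "mr_2sls")) {
          row$mr_estimate <- fit$estimate
          row$mr_se <- fit$se
          row$mr_p <- fit$p.value
          row$first_stage_F <- fit$first_stage$F
          row$mr_note <- if (length(fit$flags)) paste(fit$flags, collapse = ";")
                         else "ok"
        } else row$mr_note <- paste("error:", conditionMessage(fit))
      } else row$mr_note <- iv$flag
    }
    mr_rows[[i]] <- row
  }
  mr_onesample <- if (length(mr_rows)) do.call(rbind, mr_rows) else
    data.frame(probe_id = character(0), design = character(0),
               n_meqtls = integer(0), mr_estimate = numeric(0),
               mr_se = numeric(0), mr_p = numeric(0),
               first_stage_F = numeric(0), mr_note = character(0))

  ## 8. two-sample Wald MR over synthetic cis genes
  genes <- synthetic_gene_annotation(suggestive, config$cis_window,
                                     config$genes_per_cpg)
  wald <- NULL
  if (nrow(genes)) {
    ss <- simulate_summary_stats(
      n_genes = nrow(genes),
      true_wald_ratios = rep_len(c(0.3, 0, 0), nrow(genes)),
      flip_fraction = 0.3)
    ss$exposure$gene <- genes$gene
    harmonized <- harmonize_summary_stats(ss$exposure, ss$outcome)
    wald <- run_wald_mr(harmonized)
    cis <- do.call(rbind, lapply(seq_len(nrow(suggestive)), function(i) {
      hits <- map_cis_genes(suggestive$chrom[i], suggestive$pos[i], genes,
                            window = config$cis_window)
      if (nrow(hits)) data.frame(probe_id = suggestive$probe_id[i],
                                 gene = hits$gene, stringsAsFactors = FALSE)
      else NULL
    }))
    wald <- merge(cis, wald, by = "gene", sort = TRUE)
  }

  ## 9. GWAS-region overlap with reference-panel LD
  vt <- study$genotypes$variants
  index_default <- do.call(rbind, lapply(split(vt, vt$chrom), function(v)
    v[ceiling(nrow(v) / 2), c("variant_id", "chrom", "pos")]))
  index_default$source <- "synthetic_index"
  overlap <- overlap_gwas_regions(suggestive, index_default,
                                  window = config$cis_window)
  ld_report <- NULL
  if (nrow(overlap)) {
    panel <- genotype_matrix(
      do.call(cbind, lapply(unique(vt$chrom), function(ch)
        simulate_genotypes(config$panel_n, sum(vt$chrom == ch),
                           maf_range = config$sim$maf_range,
                           ld_block_size = config$sim$ld_block_size,
                           ld_rho = config$sim$ld_rho, chrom = ch,
                           sample_ids = sprintf("P%03d",
                                                seq_len(config$panel_n)))$dosage)),
      vt)
    ld_rows <- lapply(seq_len(nrow(overlap)), function(i) {
      key <- paste(suggestive$design[match(overlap$probe_id[i],
                                           suggestive$probe_id)],
                   overlap$probe_id[i])
      iv <- instruments[[key]]
      if (is.null(iv) || iv$flag != "ok")
        return(data.frame(probe_id = overlap$probe_id[i],
                          variant_id = overlap$variant_id[i],
                          max_r2 = NA_real_, verdict = "untestable",
                          stringsAsFactors = FALSE))
      ld <- instrument_index_ld(iv, overlap$variant_id[i], panel,
                                r2_threshold = config$meqtl_r2,
                                study_genotypes = study$genotypes,
                                study_mvalues = mvals_all[overlap$probe_id[i], ])
      data.frame(probe_id = overlap$probe_id[i],
                 variant_id = overlap$variant_id[i], max_r2 = ld$max_r2,
                 verdict = ld$verdict, stringsAsFactors = FALSE)
    })
    ld_report <- do.call(rbind, ld_rows)
  }

  ## 10. consolidated table and outputs
  consolidated <- merge(suggestive[, c("design", "probe_id", "chrom", "pos",
                                       "case_mean", "comparison_mean",
                                       "delta_beta", "p", "q")],
                        mr_onesample, by = c("design", "probe_id"), sort = TRUE)
  consolidated <- consolidated[order(consolidated$design, consolidated$p), ]
  rownames(consolidated) <- NULL

  out <- structure(list(study = study, qc_report = qc$report,
                        cell_fractions = fractions, mepcs = mepcs,
                        tuning = tuning, ewas = results,
                        suggestive = suggestive, meqtl_scans = meqtl_scans,
                        instruments = instruments,
                        mr_onesample = mr_onesample, genes = genes,
                        mr_twosample = wald, gwas_overlap = overlap,
                        gwas_ld = ld_report, consolidated = consolidated,
                        seed = seed, config = config),
                   class = "methylmr_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(stage) c(paste("methylmr pipeline stage:", stage),
                               paste("seed:", seed))
    for (nm in names(results))
      write_tsv_commented(as.data.frame(results[[nm]]),
                          file.path(out_dir, paste0("ewas_", nm, ".tsv")),
                          stamp(paste("ewas", nm)))
    write_tsv_commented(suggestive, file.path(out_dir, "suggestive.tsv"),
                        stamp("suggestive CpGs"))
    write_tsv_commented(mr_onesample, file.path(out_dir, "mr_onesample.tsv"),
                        stamp("one-sample 2SLS MR"))
    if (!is.null(wald))
      write_tsv_commented(wald, file.path(out_dir, "mr_twosample.tsv"),
                          stamp("two-sample Wald MR"))
    write_tsv_commented(overlap, file.path(out_dir, "gwas_overlap.tsv"),
                        stamp("GWAS-region overlap"))
    if (!is.null(ld_report))
      write_tsv_commented(ld_report, file.path(out_dir, "gwas_ld.tsv"),
                          stamp("instrument/index LD"))
    write_tsv_commented(consolidated, file.path(out_dir, "consolidated.tsv"),
                        stamp("consolidated per-CpG table"))
    log <- list(package = "methylmr",
                version = as.character(utils::packageVersion("methylmr")),
                r_version = R.version.string, seed = seed,
                n_samples = ncol(m$beta), n_probes = nrow(m$beta),
                lambda = lapply(results, function(r) attr(r, "lambda")),
                covariates = lapply(tuning, function(t) t$selected),
                params = unclass(config)[setdiff(names(config), "sim")])
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  }
  invisible(out)
}

#' @export
print.methylmr_pipeline <- function(x, ...) {
  cat("methylmr pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  %d samples, %d probes after QC\n",
              x$qc_report$n_samples[["after"]], x$qc_report$n_probes[["after"]]))
  for (nm in names(x$ewas))
    cat(sprintf("  %s: lambda = %.3f, covariates = %s, suggestive = %d\n", nm,
                attr(x$ewas[[nm]], "lambda"), x$tuning[[nm]]$selected,
                sum(x$suggestive$design == nm)))
  cat(sprintf("  2SLS MR: %d CpG(s) with instruments, %d with p < 0.05\n",
              sum(x$mr_onesample$n_meqtls > 0),
              sum(x$mr_onesample$mr_p < 0.05, na.rm = TRUE)))
  invisible(x)
}
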