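#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the generator with defaults that mirror the
#' published study design this package emulates: 45 moderate-to-severe
#' hypospadias cases and 46 unaffected controls, 21 cases with chordee and 9
#' severe cases (all severe cases presenting with chordee), preputial-tissue
#' cell mixture dominated by epithelial cells and fibroblasts, and a handful
#' of CpGs with strong cis-meQTLs and large causal effects on the outcome
#' liability, sized to the top published locus (a 15.7% beta-value
#' difference backed by strong instruments).
#'
#' @param n_cases,n_controls Case/control sample counts.
#' @param n_chordee Cases with chordee (<= n_cases).
#' @param n_severe Severe cases (<= n_cases). By default severe cases are
#'   nested within chordee (see \code{nest_chordee_in_severe}).
#' @param chroms Chromosome labels to simulate variants on.
#' @param n_variants_per_chrom Variants per chromosome.
#' @param n_cpgs Number of regular CpG probes (deconvolution marker probes
#'   are appended on top of these).
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param ld_block_size,ld_rho LD blocks: consecutive variants in a block
#'   share a latent Gaussian factor with correlation \code{ld_rho} in [0, 1).
#' @param meqtl_effects data.frame(cpg, variant, effect) of per-allele
#'   effects on the latent M-value, or NULL for the default planted set.
#' @param causal_cpg_effects data.frame(cpg, design, effect) of effects on
#'   the outcome liability (logit units per M), or NULL for the default.
#' @param cell_fractions_alpha Named Dirichlet concentration parameters for
#'   per-sample cell fractions.
#' @param batch_labels Batch labels cycled across samples.
#' @param batch_sd SD of per-probe batch offsets (M-value units).
#' @param noise_sd SD of probe-level measurement noise (M-value units).
#' @param nest_chordee_in_severe If TRUE (default) every severe case is
#'   assigned chordee before the remaining chordee quota is drawn from
#'   moderate cases, matching the published cross-tabulation.
#' @param location_counts data.frame(severity, location, chordee, n) giving
#'   the meatal-location cross-tabulation used to label cases, or NULL to
#'   use the published table.
#' @param seed Integer seed driving the whole generator.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_cases = 45, n_controls = 46, n_chordee = 21,
                              n_severe = 9, chroms = c("1", "2", "6"),
                              n_variants_per_chrom = 250, n_cpgs = 600,
                              maf_range = c(0.1, 0.5), ld_block_size = 10,
                              ld_rho = 0.7, meqtl_effects = NULL,
                              causal_cpg_effects = NULL,
                              cell_fractions_alpha = c(epithelial = 8, fibroblast = 6,
                                                       b_cell = 0.5, nk_cell = 0.5,
                                                       cd4t = 1, monocyte = 0.5,
                                                       neutrophil = 2, eosinophil = 0.5),
                              batch_labels = c("plate1", "plate2"),
                              batch_sd = 0.3, noise_sd = 0.6,
                              nest_chordee_in_severe = TRUE,
                              location_counts = NULL, seed = 1L) {
  counts <- c(n_cases, n_controls, n_variants_per_chrom, n_cpgs)
  if (any(counts <= 0)) stop("sample, variant and CpG counts must be positive")
  if (n_chordee > n_cases || n_severe > n_cases)
    stop("'n_chordee' and 'n_severe' cannot exceed 'n_cases'")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an increasing pair within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  if (nest_chordee_in_severe && n_chordee < n_severe)
    stop("with nested chordee, 'n_chordee' must be >= 'n_severe'")

  cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))
  if (is.null(meqtl_effects)) {
    ## three planted causal CpGs, each instrumented by three variants in
    ## well-separated LD blocks of its own chromosome, plus two CpGs with
    ## meQTLs but no causal role
    pick <- function(chrom, idx) sprintf("var%s_%04d", chrom, idx)
    idx <- pmin(c(5L, 105L, 205L), n_variants_per_chrom)
    meqtl_effects <- data.frame(
      cpg = rep(c("cg000001", "cg000002", "cg000003", "cg000004", "cg000005"),
                each = 3),
      variant = c(pick(chroms[1], idx), pick(chroms[pmin(2, length(chroms))], idx),
                  pick(chroms[pmin(3, length(chroms))], idx),
                  pick(chroms[1], pmin(idx + 20L, n_variants_per_chrom)),
                  pick(chroms[pmin(2, length(chroms))],
                       pmin(idx + 20L, n_variants_per_chrom))),
      effect = c(rep(0.8, 9), rep(0.5, 6)),
      stringsAsFactors = FALSE)
  }
  if (is.null(causal_cpg_effects)) {
    causal_cpg_effects <- data.frame(
      cpg = c("cg000001", "cg000002", "cg000003"),
      design = c("hypospadias_case_control", "chordee_case_only", "severity_case_only"),
      effect = c(2, 2, 2), stringsAsFactors = FALSE)
  }
  bad <- setdiff(c(meqtl_effects$cpg, causal_cpg_effects$cpg), cpg_ids)
  if (length(bad)) stop("planted effects reference unknown CpGs: ",
                        paste(unique(bad), collapse = ", "))
  known_designs <- c("hypospadias_case_control", "chordee_case_only",
                     "severity_case_only")
  if (!all(causal_cpg_effects$design %in% known_designs))
    stop("causal effects reference unknown design labels")
  if (is.null(location_counts)) {
    location_counts <- data.frame(
      severity = c(rep("moderate", 6), rep("severe", 4)),
      location = c("distal", "distal", "midshaft", "midshaft", "subcoronal",
                   "subcoronal", "penoscrotal", "penoscrotal",
                   "perineal_or_proximal", "perineal_or_proximal"),
      chordee = rep(c(1L, 0L), 5),
      n = c(6L, 17L, 6L, 6L, 0L, 1L, 7L, 0L, 2L, 0L),
      stringsAsFactors = FALSE)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_chordee = n_chordee, n_severe = n_severe, chroms = chroms,
                 n_variants_per_chrom = n_variants_per_chrom, n_cpgs = n_cpgs,
                 cpg_ids = cpg_ids, maf_range = maf_range,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 meqtl_effects = meqtl_effects,
                 causal_cpg_effects = causal_cpg_effects,
                 cell_fractions_alpha = cell_fractions_alpha,
                 batch_labels = batch_labels, batch_sd = batch_sd,
                 noise_sd = noise_sd,
                 nest_chordee_in_severe = nest_chordee_in_severe,
                 location_counts = location_counts, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate genotype dosages in LD blocks under Hardy-Weinberg equilibrium
#'
#' Haplotypes are generated from a Gaussian copula: consecutive variants in
#' a block share a latent factor with correlation \code{ld_rho}, each latent
#' value is thresholded at the allele-frequency quantile, and the two
#' haplotypes are added into a dosage in \code{\{0, 1, 2\}}. Marginally each
#' variant is in Hardy-Weinberg equilibrium at its drawn frequency;
#' within-block dosage correlation increases monotonically with
#' \code{ld_rho}.
#'
#' @param n_samples,n_variants Dimensions (n_samples >= 2).
#' @param maf_range Allele-frequency range within (0, 0.5].
#' @param ld_block_size,ld_rho Block size and latent block correlation.
#' @param chrom Chromosome label for the variant metadata.
#' @param pos_start,pos_step 1-based positions: \code{pos_start + (i-1) *
#'   pos_step}.
#' @param sample_ids Optional sample ids (default \code{S001, ...}).
#' @param seed Optional integer seed; fixed seeds give bit-identical output.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf_range = c(0.05, 0.5),
                               ld_block_size = 10, ld_rho = 0.7, chrom = "1",
                               pos_start = 1e6, pos_step = 5000,
                               sample_ids = NULL, seed = NULL) {
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (n_variants < 1) stop("'n_variants' must be at least 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an increasing pair within (0, 0.5]")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop("'ld_rho' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sample_ids <- sample_ids %||% sprintf("S%03d", seq_len(n_samples))

  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  n_blocks <- ceiling(n_variants / ld_block_size)
  block <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(n_variants)]
  thr <- rep(stats::qnorm(maf), each = n_samples)
  haplotype <- function() {
    shared <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    z <- sqrt(ld_rho) * shared[, block, drop = FALSE] +
      sqrt(1 - ld_rho) * matrix(stats::rnorm(n_samples * n_variants),
                                n_samples, n_variants)
    (z < thr) * 1
  }
  dosage <- haplotype() + haplotype()

  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  alle <- pairs[sample.int(nrow(pairs), n_variants, replace = TRUE), , drop = FALSE]
  variants <- data.frame(
    variant_id = sprintf("var%s_%04d", chrom, seq_len(n_variants)),
    chrom = chrom, pos = as.integer(pos_start + (seq_len(n_variants) - 1) * pos_step),
    ref = alle[, 1], alt = alle[, 2], effect_allele = alle[, 2],
    maf = maf, ld_block = block, stringsAsFactors = FALSE)
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  genotype_matrix(dosage, variants)
}

#' Synthetic cell-type reference profiles for deconvolution
#'
#' Deterministic marker-probe beta profiles for the eight cell types of a
#' mixed preputial-tissue reference (epithelial, fibroblast, B, NK, CD4 T,
#' monocyte, neutrophil, eosinophil): each type has
#' \code{n_markers_per_type} probes near-fully methylated in that type and
#' near-unmethylated in all others. Entirely synthetic - a stand-in for an
#' experimentally derived reference.
#'
#' @param n_markers_per_type Marker probes per cell type.
#' @return Markers x cell-types matrix of beta values with probe ids
#'   \code{mk_<type>_<i>} as rownames.
#' @export
default_cell_reference <- function(n_markers_per_type = 6) {
  types <- c("epithelial", "fibroblast", "b_cell", "nk_cell", "cd4t",
             "monocyte", "neutrophil", "eosinophil")
  n <- n_markers_per_type * length(types)
  ref <- matrix(0.1, n, length(types),
                dimnames = list(character(n), types))
  for (t in seq_along(types)) {
    rows <- (t - 1) * n_markers_per_type + seq_len(n_markers_per_type)
    ref[rows, t] <- 0.9
    rownames(ref)[rows] <- sprintf("mk_%s_%d", types[t], seq_len(n_markers_per_type))
  }
  ## small deterministic stagger so profiles are not exactly collinear
  ref + outer(seq_len(n) %% 5, seq_along(types), function(i, j) (i + j) %% 3) * 0.005
}

## Dirichlet draws via normalized gammas
rdirichlet_matrix <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  sweep(g, 1, rowSums(g), "/")
}

#' Simulate a methylation matrix with planted meQTL, batch and cell-mixture
#' structure
#'
#' Latent M-values are \code{baseline + sum(effect x dosage) + batch +
#' N(0, noise_sd)} and are mapped to betas with the same log2-odds link the
#' analysis pipeline inverts, so the transform round-trip is exact. Marker
#' probes of the cell-type reference are appended and carry a convex
#' combination of the reference profiles weighted by per-sample Dirichlet
#' cell fractions.
#'
#' @param genotypes A [genotype_matrix()] covering all configured
#'   chromosomes for the study samples.
#' @param config A [simulation_config()].
#' @param cell_reference Markers x cell-types reference matrix; default
#'   [default_cell_reference()].
#' @return list(methylation = [methylation_matrix()], truth = ground-truth
#'   list with the noise-free M matrix, cell fractions, per-probe batch
#'   offsets, batch assignment and the planted effect tables).
#' @export
simulate_methylation <- function(genotypes, config,
                                 cell_reference = default_cell_reference()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  unknown <- setdiff(config$meqtl_effects$variant, genotypes$variants$variant_id)
  if (length(unknown))
    stop("meQTL effects reference variants absent from the genotypes: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  samples <- rownames(genotypes$dosage)
  n <- length(samples)
  cpgs <- config$cpg_ids
  planted <- unique(config$meqtl_effects$cpg)

  ## baseline M: bimodal methylome for unplanted probes, mid-range for
  ## planted probes so beta-scale group differences are visible
  comp <- sample.int(3, config$n_cpgs, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  base_beta <- c(stats::rbeta(config$n_cpgs, 8, 2), stats::rbeta(config$n_cpgs, 2, 8),
                 stats::rbeta(config$n_cpgs, 2, 2))[seq_len(config$n_cpgs) +
                                                      (comp - 1) * config$n_cpgs]
  base_m <- beta_to_m(base_beta)
  base_m[cpgs %in% planted] <- 0.8

  ## probe coordinates: planted CpGs sit at their middle meQTL variant;
  ## the rest cycle across the configured chromosomes
  chrom <- rep_len(config$chroms, config$n_cpgs)
  span <- range(genotypes$variants$pos)
  pos <- as.integer(round(stats::runif(config$n_cpgs, span[1], span[2])))
  for (cg in planted) {
    vs <- config$meqtl_effects$variant[config$meqtl_effects$cpg == cg]
    vrow <- match(vs, genotypes$variants$variant_id)
    i <- match(cg, cpgs)
    chrom[i] <- genotypes$variants$chrom[vrow[1]]
    pos[i] <- as.integer(round(mean(genotypes$variants$pos[vrow])))
  }

  m_true <- matrix(base_m, config$n_cpgs, n, dimnames = list(cpgs, samples))
  for (k in seq_len(nrow(config$meqtl_effects))) {
    eff <- config$meqtl_effects[k, ]
    m_true[eff$cpg, ] <- m_true[eff$cpg, ] +
      eff$effect * genotypes$dosage[, eff$variant]
  }

  batch <- rep_len(config$batch_labels, n)
  names(batch) <- samples
  batch_offsets <- matrix(stats::rnorm(config$n_cpgs * length(config$batch_labels),
                                       sd = config$batch_sd),
                          config$n_cpgs, length(config$batch_labels),
                          dimnames = list(cpgs, config$batch_labels))
  ## first batch is the reference level
  batch_offsets[, 1] <- 0

  m_obs <- m_true + batch_offsets[, batch, drop = FALSE] +
    matrix(stats::rnorm(config$n_cpgs * n, sd = config$noise_sd), config$n_cpgs, n)
  beta <- m_to_beta(m_obs)

  ## marker probes: convex mixture of reference profiles plus mild noise
  alpha <- config$cell_fractions_alpha
  fractions <- rdirichlet_matrix(n, alpha)
  dimnames(fractions) <- list(samples, names(alpha))
  ref <- cell_reference[, names(alpha), drop = FALSE]
  marker_beta <- ref %*% t(fractions)
  marker_obs <- pmin(pmax(marker_beta +
                            matrix(stats::rnorm(length(marker_beta), sd = 0.01),
                                   nrow(marker_beta)), 1e-4), 1 - 1e-4)
  dimnames(marker_obs) <- list(rownames(ref), samples)

  all_beta <- rbind(beta, marker_obs)
  manifest <- data.frame(
    probe_id = rownames(all_beta),
    chrom = c(chrom, rep("22", nrow(ref))),
    pos = c(pos, as.integer(5e7 + seq_len(nrow(ref)) * 1000)),
    probe_class = "cg", snp_flag = FALSE, stringsAsFactors = FALSE)

  truth <- list(m_true = rbind(m_true, beta_to_m(marker_beta)),
                cell_fractions = fractions,
                meqtl_effects = config$meqtl_effects,
                causal_effects = config$causal_cpg_effects,
                batch = batch, batch_offsets = batch_offsets,
                marker_ids = rownames(ref))
  list(methylation = methylation_matrix(all_beta, manifest), truth = truth)
}

## odds-weighted sampling without replacement: exact quota, uniform under a
## null linear predictor, strict separation as effects grow unbounded
draw_by_odds <- function(ids, eta, size) {
  if (size <= 0) return(character(0))
  if (size >= length(ids)) return(ids)
  eta <- pmin(pmax(eta - mean(eta), -30), 30)
  sample(ids, size, prob = exp(eta))
}

#' Assign case/control status and clinical sublabels with exact counts
#'
#' Case labels follow a logistic liability on the noise-free M-values of the
#' planted causal CpGs: samples are drawn into the case group by
#' odds-weighted sampling without replacement, which fixes the group sizes
#' exactly while remaining uniform when all effects are zero. Chordee and
#' severity labels are assigned within cases the same way (severe cases are
#' nested within chordee when configured), then meatal locations are
#' distributed according to the configured cross-tabulation. Ages mimic the
#' study population: circumcision/surgery at roughly ten months of age.
#'
#' @param truth Ground-truth list from [simulate_methylation()].
#' @param config A [simulation_config()].
#' @return data.frame of class \code{"phenotype_table"} with columns
#'   \code{sample_id}, \code{hypospadias}, \code{chordee} (NA for controls),
#'   \code{severity} (NA for controls), \code{location},
#'   \code{subject_age_months}, \code{tissue_age_months}, \code{batch}.
#' @export
simulate_outcome <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  eff <- config$causal_cpg_effects
  missing_cpg <- setdiff(eff$cpg, rownames(truth$m_true))
  if (length(missing_cpg))
    stop("causal effects reference unknown CpGs: ",
         paste(missing_cpg, collapse = ", "))
  samples <- colnames(truth$m_true)
  n <- length(samples)
  if (n != config$n_cases + config$n_controls)
    stop("sample count does not equal n_cases + n_controls")

  linpred <- function(design, ids) {
    rows <- eff[eff$design == design, , drop = FALSE]
    eta <- numeric(length(ids))
    for (k in seq_len(nrow(rows))) {
      m <- truth$m_true[rows$cpg[k], ids]
      eta <- eta + rows$effect[k] * (m - mean(m))
    }
    eta
  }

  cases <- draw_by_odds(samples, linpred("hypospadias_case_control", samples),
                        config$n_cases)
  severe <- draw_by_odds(cases, linpred("severity_case_only", cases),
                         config$n_severe)
  if (config$nest_chordee_in_severe) {
    moderate <- setdiff(cases, severe)
    chordee <- c(severe, draw_by_odds(moderate, linpred("chordee_case_only", moderate),
                                      config$n_chordee - config$n_severe))
  } else {
    chordee <- draw_by_odds(cases, linpred("chordee_case_only", cases),
                            config$n_chordee)
  }

  is_case <- samples %in% cases
  pheno <- data.frame(
    sample_id = samples,
    hypospadias = as.integer(is_case),
    chordee = ifelse(is_case, as.integer(samples %in% chordee), NA_integer_),
    severity = ifelse(is_case, ifelse(samples %in% severe, "severe", "moderate"),
                      NA_character_),
    location = NA_character_, stringsAsFactors = FALSE)

  ## meatal locations per configured (severity, chordee) cross-tabulation
  loc <- config$location_counts
  for (sev in unique(loc$severity)) for (ch in unique(loc$chordee)) {
    cell <- loc[loc$severity == sev & loc$chordee == ch & loc$n > 0, , drop = FALSE]
    pool <- sample(pheno$sample_id[!is.na(pheno$chordee) & pheno$chordee == ch &
                                     pheno$severity == sev])
    labels <- rep(cell$location, cell$n)
    k <- min(length(pool), length(labels))
    if (k > 0) pheno$location[match(pool[seq_len(k)], pheno$sample_id)] <-
        labels[seq_len(k)]
  }

  pheno$subject_age_months <- round(pmax(stats::rnorm(
    n, mean = ifelse(is_case, 10.1, 10.7), sd = 2.5), 3), 1)
  pheno$tissue_age_months <- round(stats::runif(n, 6, 36), 1)
  pheno$batch <- unname(truth$batch[samples])
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}

#' Tabulate case characteristics as n (percent)
#'
#' Summarizes the case series the way descriptive case tables are printed:
#' counts and percentages of all cases, cross-tabulated by severity, meatal
#' location and chordee presence.
#'
#' @param phenotype A phenotype table from [simulate_outcome()].
#' @param digits Decimal places for percentages (default 1).
#' @return data.frame(severity, location, chordee, n, pct).
#' @export
phenotype_summary <- function(phenotype, digits = 1) {
  cases <- phenotype[phenotype$hypospadias == 1, , drop = FALSE]
  tab <- as.data.frame(table(severity = cases$severity, location = cases$location,
                             chordee = cases$chordee), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  data.frame(severity = tab$severity, location = tab$location,
             chordee = as.integer(tab$chordee), n = tab$Freq,
             pct = percent_of(tab$Freq, nrow(cases), digits),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Runs the generator end to end under a single seed: genotypes per
#' chromosome, methylation with planted meQTL/batch/cell-mixture structure,
#' and phenotype labels with exact group counts.
#'
#' @param config A [simulation_config()].
#' @param cell_reference Reference profile matrix, default
#'   [default_cell_reference()].
#' @return list(genotypes, methylation, truth, phenotype, config).
#' @export
simulate_study <- function(config = simulation_config(),
                           cell_reference = default_cell_reference()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  sample_ids <- sprintf("S%03d", seq_len(n))
  per_chrom <- lapply(seq_along(config$chroms), function(i) {
    simulate_genotypes(n, config$n_variants_per_chrom,
                       maf_range = config$maf_range,
                       ld_block_size = config$ld_block_size,
                       ld_rho = config$ld_rho, chrom = config$chroms[i],
                       pos_start = 1e6, pos_step = 5000,
                       sample_ids = sample_ids)
  })
  genotypes <- genotype_matrix(
    do.call(cbind, lapply(per_chrom, function(g) g$dosage)),
    do.call(rbind, lapply(per_chrom, function(g) g$variants)))
  meth <- simulate_methylation(genotypes, config, cell_reference)
  phenotype <- simulate_outcome(meth$truth, config)
  list(genotypes = genotypes, methylation = meth$methylation,
       truth = meth$truth, phenotype = phenotype, config = config)
}

#' Simulate paired exposure/outcome summary statistics with known Wald ratios
#'
#' One instrument per gene: exposure (eQTL-style) effects are drawn away
#' from zero, outcome (GWAS-style) effects are \code{ratio x exposure +
#' N(0, outcome_noise_sd)}. A configurable fraction of outcome records has
#' its alleles flipped (effect negated, alleles swapped) to exercise
#' harmonization, and a fraction of variants can be made palindromic (A/T).
#'
#' @param n_genes Number of gene records.
#' @param true_wald_ratios Planted causal ratio(s), recycled over genes.
#' @param exposure_se,outcome_se Reported standard errors.
#' @param outcome_noise_sd SD of the noise added to outcome betas (default
#'   \code{outcome_se}; set 0 for exact planted ratios).
#' @param flip_fraction Fraction of outcome records stored on the opposite
#'   strand orientation.
#' @param palindromic_fraction Fraction of variants given A/T alleles.
#' @param tissue Tissue label for the exposure records.
#' @param seed Optional integer seed.
#' @return list(exposure, outcome) of summary-statistic data.frames with
#'   columns variant_id, chrom, pos, effect_allele, other_allele, beta, se,
#'   p (exposure additionally gene, tissue) plus a \code{true_ratio} column
#'   on the exposure side.
#' @export
simulate_summary_stats <- function(n_genes, true_wald_ratios = 0,
                                   exposure_se = 0.05, outcome_se = 0.05,
                                   outcome_noise_sd = outcome_se,
                                   flip_fraction = 0, palindromic_fraction = 0,
                                   tissue = "tissue_a", seed = NULL) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (flip_fraction < 0 || flip_fraction > 1 ||
      palindromic_fraction < 0 || palindromic_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ratio <- rep_len(true_wald_ratios, n_genes)
  b_x <- sample(c(-1, 1), n_genes, replace = TRUE) * stats::runif(n_genes, 0.3, 0.8)
  se_x <- rep_len(exposure_se, n_genes)
  b_y <- ratio * b_x + stats::rnorm(n_genes, sd = outcome_noise_sd)
  se_y <- rep_len(outcome_se, n_genes)

  n_pal <- round(palindromic_fraction * n_genes)
  ea <- c(rep("A", n_pal), sample(c("A", "G", "C", "T"), n_genes - n_pal,
                                  replace = TRUE))
  oa <- c(rep("T", n_pal),
          vapply(ea[seq_len(n_genes - n_pal) + n_pal], function(a)
            switch(a, A = "G", T = "C", G = "A", C = "T"), ""))

  exposure <- data.frame(
    variant_id = sprintf("iv%05d", seq_len(n_genes)),
    chrom = as.character(rep_len(1:22, n_genes)),
    pos = as.integer(1e6 + seq_len(n_genes) * 1e4),
    effect_allele = ea, other_allele = oa,
    beta = b_x, se = se_x, p = 2 * stats::pnorm(-abs(b_x / se_x)),
    gene = sprintf("GENE%04d", seq_len(n_genes)), tissue = tissue,
    true_ratio = ratio, stringsAsFactors = FALSE)

  outcome <- data.frame(
    variant_id = exposure$variant_id, chrom = exposure$chrom, pos = exposure$pos,
    effect_allele = ea, other_allele = oa,
    beta = b_y, se = se_y, p = 2 * stats::pnorm(-abs(b_y / se_y)),
    stringsAsFactors = FALSE)
  flip <- seq_len(round(flip_fraction * n_genes))
  if (length(flip)) {
    outcome$effect_allele[flip] <- oa[flip]
    outcome$other_allele[flip] <- ea[flip]
    outcome$beta[flip] <- -outcome$beta[flip]
  }
  list(exposure = exposure, outcome = outcome)
}
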