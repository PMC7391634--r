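Package: methylmr
Title: Integrative Methylome-Genome Causal Analysis for Hypospadias-Style
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Epigenome-wide association scans (case-control and case-only
    designs), methylation quantitative trait locus (meQTL) mapping with
    greedy LD-based instrument pruning, one-sample two-stage least squares
    Mendelian randomization of CpG methylation on a binary outcome, cis-gene
    two-sample Wald-ratio Mendelian randomization on summary statistics, and
    GWAS-region cross-referencing. Includes reference-based cell-type
    deconvolution, surrogate-variable and methylation-PC construction with
    genomic-inflation-driven covariate tuning, and a synthetic-data
    generator with known ground truth so the full pipeline is testable
    without access to individual-level study data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
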