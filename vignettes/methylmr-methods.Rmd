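---
title: "Models and design choices in methylmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methylmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methylmr` implements an integrative methylome–genome causal pipeline for a
small case–control study of a binary urogenital outcome: epigenome-wide
association scans in three designs, methylation quantitative trait locus
(meQTL) mapping, one-sample two-stage least squares Mendelian randomization
(2SLS MR) of CpG methylation on the outcome, two-sample Wald-ratio MR of
cis-gene expression, and cross-referencing with published GWAS regions.
This vignette records the statistical models, their assumptions, the
parameters that matter, and the design decisions that were genuinely open.

## Scales: beta values and M-values

A CpG's methylation fraction (beta, in $[0,1]$) is variance-unstable near
the boundaries; the M-value $M = \log_2\big(\beta/(1-\beta)\big)$ is the
standard variance-stabilized regression scale. The package clips betas into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-3}$ before the
transform; inside that region `m_to_beta(beta_to_m(x))` is exact to
$10^{-12}$. Group scans run on betas (group mean betas and their difference
are the reported, interpretable effect sizes); meQTL scans and MR run on
M-values. Group means are always reported on the beta scale, with
`delta_beta = comparison mean − case mean`, so a case group with *lower*
methylation yields a *positive* delta.

## Quality control

Samples are removed when the fraction of probes failing detection
(detection $p > 0.01$) exceeds 5%, or when flagged as sex-mismatched
(sex prediction is upstream of this package; the filter accepts
precomputed flags). Probes are removed when bead-failed in ≥ 5% of
samples, non-CpG (`ch`/`rs` classes), SNP-associated, or detection-failed
in ≥ 5% of samples. The wording "samples were filtered to have detection
P > 0.01" in study descriptions of this kind is not executable literally;
the conventional reading implemented here is a per-sample failure-rate
threshold. Filtering is idempotent and every removal is recorded with a
reason.

## Cell-type deconvolution

Bulk preputial tissue is a mixture of epithelial cells, fibroblasts and
blood cells. Fractions are estimated per sample by non-negative least
squares (Lawson–Hanson, via `pracma::lsqnonneg`) of the sample's
marker-probe betas on reference profiles, truncated at zero and
renormalized to sum to one. A Huber-weighted variant (`method = "huber"`,
tuning constant 1.345 in residual-MAD units) down-weights outlying markers.
This is the same estimand as robust-partial-correlation deconvolution but
with a simpler, exactly testable contract: noiseless mixtures are recovered
to numerical precision, and the shipped synthetic reference
(`default_cell_reference()`, 6 markers per type, near-binary profiles) is
labelled synthetic — it stands in for an experimentally derived reference
and carries none of the biology of a real one.

## Surrogate variables and methylation PCs

Unmeasured batch/technical structure is absorbed by surrogate variables.
Factor *discovery* runs on the matrix residualized on the protected design
(the outcome must not drive which directions are found): the top right
singular vectors of the residual matrix give probe loadings. The surrogate
variables themselves are the projections of the **raw** centered data onto
those loadings, orthonormalized. The raw-data projection is essential, and
is the one place the package deliberately departs from a purely
residual-space construction: a factor that is partially confounded with the
outcome (by chance or by design) must retain its outcome-overlapping
component, because a surrogate variable constrained orthogonal to the
outcome provably cannot remove the confounding bias such a factor induces —
adjusting for it only shrinks standard errors and *worsens* the genomic
inflation. With the raw-data projection, a strongly confounded planted
batch factor is recovered almost exactly and its inflation is removed,
which is what the calibration tests assert.

The number of factors (`k = "auto"`) is chosen by permutation parallel
analysis: each probe's residuals are permuted across samples $B = 100$
times and components are kept, contiguously from the first, while the
observed singular value exceeds the permutation quantile of the same order
statistic. The default quantile is **0.99**, not the conventional 0.95: the
permutation null is conditional on the realized matrix and is
anti-conservative for the leading singular value — at 0.95 a pure-noise
matrix retains a spurious component in roughly one run in six, while at
0.99 (with $B = 100$) the spurious-retention rate is a few percent, which
the null property test asserts.

Methylation PCs are the usual top-$k$ left singular vectors of the
column-centered data, scores scaled by singular values, with
variance-explained in non-increasing order.

### Why the default pipeline does not stack mePCs into the EWAS

In a full-size methylome (hundreds of thousands of probes), one CpG
contributes negligibly to any global PC. In the scaled-down synthetic
methylome used here (600 CpGs), a strong causal CpG loads visibly on the
global PCs, so the PCs carry a non-negligible outcome-proxy component.
Jointly adjusting for design-protected SVs *and* global mePCs then
partials the SV-space out of the mePCs and leaves almost pure outcome
proxy, which absorbs the causal signal. The default pipeline therefore
tunes the EWAS over {none, SVs, SVs + cell fractions + ages} and reserves
mePCs for the meQTL stage, where no case/control contrast is at stake.
`tune_covariates()` accepts arbitrary candidate sets, so an analysis of a
full-size methylome can include mePC candidates as published studies do.
This is a limitation of the scaled simulation, not of the estimators.

## EWAS

Per CpG, ordinary least squares of beta on the group indicator plus
covariates, classical (homoskedastic) standard errors, two-sided $t$
p-values (an HC1 robust-SE option is available). The three designs are
case–control (all samples), chordee case-only and severity case-only
(cases only). Calibration is monitored by the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_1)/0.4549$; `tune_covariates()` scans a
candidate list of covariate sets and selects the one minimizing
$|\lambda - 1|$, breaking ties toward fewer covariates, with the full
trace logged. Multiple testing is controlled within each design by
Benjamini–Hochberg FDR over the tested (non-constant) probes, via
`stats::p.adjust`; the suggestive thresholds default to FDR < 0.20 for the
case–control scan and the stricter 0.15 for the case-only scans, whose
comparison groups are small enough that false positives would otherwise
dominate. Constant probes return NA and are excluded from the FDR. A
candidate-CpG lookup classifies externally reported CpGs as absent from
the array, failed QC, or tested (with effect and p).

## meQTL mapping and instruments

For each suggestive CpG, every same-chromosome variant is tested by OLS of
the CpG's M-values on effect-allele dosage plus methylation PCs, computed
via Frisch–Waugh residualization (identical to the full per-variant OLS,
scanned in one pass). A frequentist OLS scan replaces the original
score-test tooling; at these sample sizes the two are equivalent and OLS
is exactly testable against closed forms. No multiple-testing correction
is applied within the scan — instruments are selected at the fixed
threshold $P < 10^{-3}$, then pruned greedily in ascending-p order
(deterministic tie-break by p, chromosome, position, id), accepting a
variant only if its in-sample $r^2$ with every accepted variant is below
0.2. This is standard clumping semantics; the greedy result provably
equals the stepwise definition, which the oracle tests check. In-sample
LD is the default (a reference-panel matrix can be supplied instead).
Empty sets are flagged `no_instruments`, never silently dropped.

## One-sample 2SLS MR

Stage one regresses M-values on the instrument dosages; stage two
regresses the binary outcome on the fitted M-values — a linear probability
model, matching the least-squares formulation the original analysis used
(a logistic control-function variant would be a natural extension but is
not the default). The causal estimate is the stage-two coefficient;
classical 2SLS standard errors use residuals computed from the *observed*
exposure, $y - X\hat\beta$, with $t$ on $n - k$ degrees of freedom.
Covariates default to none (the published formulation states none); any
matrix can be supplied and enters both stages. Just-identified fits equal
the ratio $\mathrm{cov}(G,Y)/\mathrm{cov}(G,M)$ to $10^{-10}$, and the
summary-level Wald ratio on the same data agrees to $10^{-8}$ — both are
asserted by tests. First-stage diagnostics report the partial $F$ and
$R^2$; fits with $F < 10$ are flagged `weak_instrument`, and a numerically
perfect first stage caps $F$ at $10^{12}$.

One property worth stating plainly: with several instruments of moderate
joint strength, the classical 2SLS $t$-test is slightly oversized under
confounding — the estimator's finite-sample bias toward OLS is of order
$(k-2)/F$. The calibration suite measures size under a strong first stage
($F \approx 100$), where the test is nominal; at $F \approx 25$ users
should expect mild overrejection. This is a property of 2SLS itself, not
of the implementation.

## Two-sample Wald-ratio MR

Genes are mapped in cis by interval overlap with the ±500 kb window around
the CpG (inclusive bounds, 1-based coordinates; interval overlap rather
than TSS distance is the default because gene bodies, not just promoters,
fall "within 500 kb" — a TSS mode is available). Exposure and outcome
summary statistics are harmonized to the exposure's effect allele: swapped
records have the outcome beta negated, palindromic (A/T, C/G) variants are
dropped because strand cannot be resolved without allele frequencies
(fixtures carry none), and mismatched allele pairs are dropped; the action
is recorded per record and harmonization is idempotent. The Wald ratio is
$\hat\theta = \beta_Y/\beta_X$ with first-order delta-method SE
$se_Y/|\beta_X|$ (a second-order option adds the exposure-uncertainty
term), normal two-sided p, one result per (gene, tissue) record.
Significance at $p < 0.05$ is flagged, never filtered on.

## GWAS-region overlap

Suggestive CpGs are paired with index variants within ±500 kb on the same
chromosome (inclusive, symmetric). For paired CpGs, each instrument's
$r^2$ with the index variant is computed in a reference panel; the verdict
is `linked` when the maximum reaches 0.2 — the same threshold as the
pruning bound, since no explicit linkage threshold is conventional —
`independent` otherwise, `untestable` when the index variant is absent
from the panel. When study genotypes are available the direct
index-variant meQTL p-value is reported alongside.

## The synthetic-data generator

The generator defines the study conditions and is first-class, tested
code. Defaults mirror the emulated study: 45 cases / 46 controls, 21 cases
with chordee, 9 severe cases (nested within chordee, matching the
published cross-tabulation, including the meatal-location table used by
`phenotype_summary()`), subject ages near 10 months.

* **Genotypes** — Gaussian-copula haplotypes thresholded at the
  allele-frequency quantile and summed: Hardy–Weinberg marginals, block-LD
  with latent correlation `ld_rho` (default 0.7, blocks of 10), MAF drawn
  from (0.1, 0.5).
* **Methylation** — latent $M = \text{baseline} + \sum \gamma\,G +
  \text{batch} + N(0, \sigma)$, mapped to betas by the same log2-odds link
  the pipeline inverts (round-trip exact). Baselines are bimodal
  (beta-mixture) as real methylomes are; planted CpGs sit mid-range so
  beta-scale differences are visible. Batch offsets are per-probe
  $N(0, 0.3)$; measurement noise is $\sigma = 0.6$ M-units.
* **Cell mixture** — Dirichlet fractions (epithelial/fibroblast dominant,
  as in preputial tissue) applied as a convex combination of reference
  profiles at the marker probes.
* **Outcome** — a logistic liability on the noise-free M-values of the
  planted causal CpGs. Case labels are drawn by odds-weighted sampling
  without replacement, which fixes the group counts exactly (the published
  design table is reproduced verbatim), reduces to uniform labelling under
  null effects, and approaches strict separation as effects grow
  unbounded. Using noise-free M cleanly separates measurement noise from
  causal signal in recovery tests.
* **Planted effects** — three causal CpGs (one per design), each
  instrumented by three variants in separate LD blocks with 0.8 M-units
  per allele, and a liability effect of 2 logits per M-unit. These sizes
  were chosen once to match the scale of the strongest published locus
  (a 15.7% beta-value difference with very strong instruments and 2SLS
  $p \sim 10^{-14}$); weaker choices would describe a study this design
  could not have detected.
* **Summary statistics** — one instrument per gene with planted Wald
  ratios, optional allele flips and palindromic variants to exercise
  harmonization.

**Problem sizes.** The default methylome is 600 CpGs plus 48 marker probes
over three chromosomes of 250 variants — the package's own choice of a
scale at which the full pipeline, including permutation parallel analysis
and twenty-seed end-to-end replications, runs comfortably on one CPU.
What scales down faithfully: estimator calibration, instrument pruning,
QC, MR identities. What does not: the FDR landscape of an 800k-probe scan
(the BH threshold here is far more permissive per probe), the PC-loading
dilution discussed above, and LD patterns of real populations
(block-constant copula LD has no recombination-map texture). Passing tests
therefore validate the estimators and their composition, not effect sizes
one should expect in new data.

## Numerical choices and degenerate inputs

Beta clipping $\varepsilon = 10^{-3}$; QR-based least squares throughout
(no normal-equation inversions on data matrices); rank-deficient designs
and collinear instruments are hard errors naming the offending columns;
monomorphic variants and constant probes return NA with warnings;
zero-dosage-variance LD is an error rather than NA; fully tied rank tests
report the maximal attainable p of 1; degenerate all-zero NNLS fits fall
back to uniform fractions with a warning. All tables are TSV with
`#`-prefixed provenance headers, 1-based inclusive coordinates, and an
explicit effect-allele column in every genetic table. Every stochastic
component accepts a seed; the pipeline derives all stage randomness from a
single `--seed`.

## Known limitations

* The stage-two linear probability model estimates risk differences, not
  odds ratios; fitted probabilities are unconstrained.
* No pleiotropy-robust MR (Egger, weighted median) — single-IV and
  plain 2SLS only, matching the emulated analysis.
* Deconvolution assumes the reference spans the tissue's true cell types;
  the shipped reference is synthetic.
* The covariate-tuning criterion ($|\lambda - 1|$) is itself noisy at a
  few hundred probes; with small methylomes its selections near the null
  are effectively arbitrary among well-calibrated sets.
* GWAS-region analysis is LD cross-referencing only; no formal mediation
  model is fitted.
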