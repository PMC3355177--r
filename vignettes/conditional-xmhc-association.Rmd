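---
title: "Conditional association analysis of the extended MHC: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional association analysis of the extended MHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmhcscan)
```

## The statistical problem

The extended MHC on chromosome 6p carries, for celiac disease, both the
strongest known genetic risk factors — the HLA-DQ2.5 and DQ8 heterodimers
determined by the *HLA-DQA1*/*HLA-DQB1* allele pair on each haplotype —
and extensive long-range linkage disequilibrium. A naive per-SNP scan of
the region is therefore uninterpretable: hundreds of SNPs reach extreme
significance merely by correlation with the DQ risk genotypes. The
analysis implemented by this package conditions the scan on an informative
encoding of the known risk and then asks how many *independent* signals
remain.

## The risk-stratum tree

### Predictor encoding

Each sample's unordered DQ haplotype-class pair over
{DQ2.5, DQ2.2, DQ7, DQ8, X} is reduced to effective copy counts by
`dq_profile()`. The biologically salient subtlety is the trans-encoded
heterodimer: a DQ2.2 haplotype and a DQ7 haplotype jointly produce the
DQ2.5 molecule across chromosomes, so the pair {DQ2.2, DQ7} is counted as
one effective DQ2.5 copy and zero DQ2.2/DQ7 copies. The tree is fitted on
the two ordinal counts `n_dq25` and `n_dq8` (0–2 each). This encoding was
chosen because the five published risk strata — DQ2.5 homozygote,
DQ2.5/DQ8, DQ2.5/non-DQ8, DQ8 carrier, and neither — are exactly
expressible in these two counts, whereas the raw multi-locus genotype
categories are not needed to reach them and carry sparse cells.

### Fitting procedure

`fit_ctree()` follows the two-stage conditional-inference scheme:

1. *Variable selection.* At each node every predictor is tested for
   independence against case/control status: Pearson chi-square with
   `levels − 1` df for nominal predictors, the 1-df trend statistic
   `N·cor(x, y)²` (the Cochran–Armitage form with linear scores) for
   ordinal ones. The minimum p-value is Bonferroni-multiplied by the
   number of predictors actually testable at the node (those with at
   least two observed values). If the adjusted p-value is not below
   `alpha` the node becomes terminal.
2. *Splitting.* The selected predictor is split at the binary partition
   maximizing the two-sample chi-square: the `k − 1` cutpoints for an
   ordinal predictor, all `2^(k−1) − 1` two-set partitions for a nominal
   one. Partitions leaving a child below `min_node` are inadmissible; if
   none is admissible the node is terminal.

We use the unconditional (multinomial, `N`-denominator) normalisation of
the quadratic-form statistics, which makes the nominal case *exactly*
Pearson's chi-square; the permutation-framework conditional variance
differs only by the factor `(N−1)/N` and is asymptotically identical. The
reference distribution is the asymptotic chi-square throughout — node
sizes in this application are in the hundreds, where the asymptotic and
Monte-Carlo permutation p-values agree to well within the decision
thresholds in play.

Splitting stops when the adjusted global null can *no longer* be rejected
— the standard stopping rule of the framework (its inversion would yield
infinite trees).

Defaults: `alpha = 0.05` (the conventional pre-specified threshold),
`min_split = 20`, `min_node = 7`. The two size limits are deliberately
small relative to a cohort of thousands; they exist to keep degenerate
micro-nodes out of the stratum covariate, not to prune.

### The worked example

The packaged `dq_stratum_counts()` table (1668 cases, 517 controls across
the five strata) can be expanded to 2185 individuals with
`dq_reference_cohort()` and refitted. The fitted tree has exactly five
terminal nodes matching the published counts, and the largest accepted
split p-value is 0.00226 — the DQ8-carrier versus neither split inside the
non-DQ2.5 branch — consistent with the published statement that all splits
fall below 0.003. One reconstruction detail is not determined by the
printed table: the DQ8-carrier stratum mixes one and two DQ8 copies. We
fix its composition deterministically (12/124 cases and 9/91 controls
homozygous, about 10%, in line with the DQ8 haplotype frequency) with
near-identical case rates in the two subgroups, matching the observation
that this node could not be split further.

## Association models

`fit_logistic()` is a Newton/IRLS maximiser with step-halving, so the
deviance trace is non-increasing by construction; convergence is declared
when the maximum absolute score falls below `1e-8`. The covariance is the
inverse observed information. Separation — coefficients drifting beyond
any plausible per-allele effect (|β| > 10) with either a non-vanishing
score or fitted probabilities pinned at 0/1 — is flagged and the CI set to
non-finite rather than silently reported. Wald tests (`z² = (β/se)²` on 1
df) and `exp(β ± 1.96·se)` intervals are reported, matching the convention
of the standard GWAS toolchain; stratum covariates enter as indicator
variables with the most frequent stratum as reference.

Missing genotypes are handled complete-case per SNP — no imputation is
attempted, and a SNP monomorphic in its analysis subset yields an `NA` row
with a reason code rather than a fit. An optional covariate SNP (the
analog of a known tag of the *HLA-DQB1* risk allele) can be forced into
every model; it is never tested against itself and is barred from clump
index status, so a known signal cannot be rediscovered as a new locus.
Whether such a SNP exists depends on the panel; the synthetic cohorts do
not emit HLA tag SNPs, so the pipeline default is none.

## LD clumping and sensitivity

Pairwise r² between unphased genotype vectors is estimated by the
two-locus EM algorithm over the double-heterozygote phase ambiguity and
converted as `r² = D²/(pA qA pB qB)`, computed in the full QC-passed
cohort (cases and controls pooled, as LD panels conventionally are). The
EM solution equals the genotype-likelihood ML estimate; note it can
differ from the phased-truth count by the information lost in double
heterozygotes (about ±0.005 at n = 5000 for r² ≈ 0.5), which bounds how
closely any unphased estimator can track phased truth.

`clump()` is the greedy grouping: SNPs in ascending p-value order (ties
broken by position then id) become indices when `p < p1` and unassigned;
each index sweeps all unassigned SNPs with `p < p2`, within `max_kb`, and
`r² ≥ r2_min` into its clump. Assignment is exclusive — the groups are
meant to be read as disjoint loci. Defaults `p1 = 5e-7`, `p2 = 0.01`,
`max_kb = 250`, `r2_min = 0.1` are the deliberately conservative published
operating point. `sensitivity_sweep()` re-runs the procedure along an r²
grid (0.05–0.95 and a fine 0.01–0.15 sub-grid) and a `−log10(p1)` grid
(4–12): requiring higher r² fragments groups (index counts non-decreasing
in r²), and raising the index threshold beyond the best SNP's significance
drives the count to zero.

## The synthetic cohort generator

`simulate_cohort()` exists so the whole pipeline can be exercised against
ground truth without any cohort download. What it emulates, and how:

* **Haplotype blocks.** Within a block, adjacent SNPs form a first-order
  Markov chain whose pairwise D is chosen to hit a target r² at the
  realized allele frequencies; blocks are mutually independent, an
  idealized recombination hotspot at every boundary. Since r² between
  biallelic loci is bounded by their allele-frequency mismatch, the
  default panel gives each block a narrow MAF band (±15% or less,
  shrunk as needed for feasibility) around a block-level anchor drawn
  from U(0.15, 0.45) — which is also the realistic regime: SNPs in strong
  LD necessarily have similar frequencies. Requesting an infeasible
  (r², MAF) combination is an error naming the feasible bound, not a
  silent clamp.
* **HLA risk.** Each individual draws two haplotype classes independently
  from `default_hla_freqs()`; disease follows a logistic model whose
  linear predictor sums a baseline (log(212/258)), the stratum effect,
  and the planted SNP effects. Stratum log-odds are the published
  five-level table's case/control odds relative to the
  non-DQ2.5/non-DQ8 stratum; the class frequencies were calibrated once
  so the expected stratum-by-status composition of sampled cases and
  controls reproduces that table to within 0.006 per cell.
* **Ascertainment.** Case/control quotas are filled by explicit rejection
  sampling — accepted individuals in draw order — making the
  case-control design exact rather than approximated by weighting.
* **Planted truth.** The default panel (95 blocks × 20 SNPs spanning
  positions 26,000,508–33,544,122, within-block adjacent r² = 0.6) plants
  four independent risk SNPs at ORs 1.7, 1.9, 2.0, 2.2 in widely
  separated blocks, with anchor MAFs 0.32–0.42 so each is well powered at
  the 5×10⁻⁷ index threshold.

What the generator does **not** emulate: coalescent genealogies and
realistic allele-frequency spectra, genotyping error, HLA tag SNPs (the
HLA locus influences risk only through the stratum variable and is not
present in the SNP panel), relatedness, or population structure. Passing
tests therefore demonstrate the statistical machinery — encoding,
stopping behavior, adjustment, grouping — under controlled conditions,
not robustness to those real-data complications.

A property worth knowing when interpreting recovery results: at the
calibrated effect sizes the weakest published split has about 86% power
under the alpha = 0.05 stopping rule, so a freshly drawn cohort recovers
the full five-node tree in roughly two thirds of draws (and a four-node
tree, merging the least-informative pair, otherwise). This is a feature of
the published effect sizes at this cohort size, not of the implementation;
the packaged default-seed cohort recovers all five strata and all four
planted loci.

## Numerical and degenerate-input choices

* Exact Hardy–Weinberg test: conditional enumeration over heterozygote
  counts given the allele counts, in log space with normalization against
  the modal configuration; the p-value sums configurations no more
  probable than observed (with a 1+1e-10 tie tolerance). Monomorphic
  variants return p = 1.
* QC order is fixed: sample call rate first, then variant call rate, MAF
  (on non-missing calls of retained samples) and HWE. HWE is computed in
  controls by default, since disease association itself distorts HWE in
  cases; `hwe_population = "all"` is available.
* Minor alleles are defined per dataset from pooled cases and controls;
  50/50 ties go to the lexicographically smaller allele, so orientation
  is deterministic.
* Tie-breaks everywhere are deterministic (p-value, then position, then
  id for clumping; first-encountered maximum for split search), making
  every pipeline stage a pure function of its inputs — re-running a
  configuration reproduces outputs byte-for-byte.
* EM for r² runs to a 1e-12 frequency tolerance (≤ 200 iterations);
  monomorphic pairs return `NA` with a reason rather than 0.

## Problem sizes used in the shipped checks

The test suite and the analysis scripts run the full pipeline at the
reference scale (2185 samples × 1900 SNPs) once, and use smaller panels
(tens of SNPs, hundreds to 2000 samples, 20–100 replicates) for
calibration and property checks: null type-I error of the stopping rule at
n = 2000 over 100 replicates, scan p-value uniformity over three
effect-free 2000-sample cohorts of 400 independent SNPs, and power/bias of
the planted-effect estimator over 100 replicates of a 1500/500 cohort.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bounds while keeping the default test run fast.

## Known limitations

* The tree's asymptotic reference is inappropriate for very small nodes;
  with the default `min_split` this regime is not reached, but users
  fitting on small cohorts should lower `alpha` expectations accordingly.
* The stratum covariate absorbs the *common* DQ risk configurations; rare
  high-risk genotypes inside a stratum leave residual confounding that a
  conditional analysis of this kind cannot remove — the motivation for
  the optional covariate SNP.
* Clumping is greedy and exclusive; it estimates the number of
  independent loci but is not a joint conditional model (no stepwise
  conditional refitting is attempted beyond the final joint logistic
  models).
* `r2_em` assumes Hardy–Weinberg proportions when resolving
  double-heterozygote phase, as all genotype-EM LD estimators do.
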