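# xmhcscan

Conditional case-control association analysis of the extended MHC (xMHC)
region, for studies — celiac disease being the motivating case — where the
known HLA-DQ high-risk genotypes dominate every naive scan of chromosome
6p and must be encoded and adjusted for before independent signals can be
seen.

## The problem and the method

More than 90% of celiac disease cases carry the HLA-DQ2.5 heterodimer
(encoded in cis on one haplotype, or in trans by a DQ2.2/DQ7 genotype) and
most of the rest carry DQ8. Any logistic scan of SNPs across the ~7.6 Mb
xMHC is therefore swamped by long-range LD with *HLA-DQA1*/*HLA-DQB1*. The
pipeline implemented here:

1. **Encodes the known risk** — each sample's DQ haplotype-class pair
   (DQ2.5, DQ2.2, DQ7, DQ8, X) becomes effective copy counts
   `(n_dq25, n_dq8)`, counting the DQ2.2/DQ7 trans combination as one
   DQ2.5 copy.
2. **Builds a risk-stratum covariate** by conditional-inference recursive
   partitioning: at each node the predictor most associated with
   case/control status (chi-square for nominal, 1-df trend for ordinal
   predictors, Bonferroni-adjusted across predictors) is split at the
   binary partition maximizing the two-sample chi-square; splitting stops
   when the adjusted global test is no longer significant at alpha = 0.05.
   The terminal nodes — five of them for this disease — become a
   categorical covariate that absorbs the known HLA effects without
   sub-sampling.
3. **Scans** all SNPs with additive (0/1/2 minor-allele) logistic
   regression, simple and stratum-adjusted, using the package's own
   iteratively reweighted least squares core.
4. **Groups correlated signals** into independent loci by greedy LD
   clumping (index p < 5×10⁻⁷, secondary p < 0.01, 250 kb window,
   r² ≥ 0.1, with r² estimated by two-locus EM over the
   double-heterozygote phase ambiguity), and sweeps those parameters to
   show the result is not an artifact of the thresholds.
5. **Verifies independence** of the index SNPs in joint multi-SNP models
   with and without the stratum covariate.

Standard QC (98% call rate, MAF ≥ 0.03, exact Hardy-Weinberg p ≥ 10⁻⁵ in
controls) precedes everything. Because the original cohort is not public,
the package ships a synthetic-cohort generator with haplotype-block LD,
recombination-hotspot boundaries, HLA-stratum disease risk calibrated to
the published five-level stratum table, and planted risk SNPs with known
effect sizes, so every stage is testable against ground truth.

## Worked example

The five-level stratum table of the reference celiac cohort (1668 cases,
517 controls) is packaged as printed counts; refitting the tree on the
reconstructed 2185 individuals reproduces the published partition:

```r
library(xmhcscan)
rc   <- dq_reference_cohort()
tree <- fit_ctree(rc$profiles, rc$y)
print(tree)
#> conditional-inference risk-stratum tree: 5 terminal nodes
#> split n_dq25 <= 0  (chi2 = 413.48, p = 1.88e-91)
#>   split n_dq8 <= 0  (chi2 = 9.32, p = 0.00226)
#>     * stratum 1 [n_dq25<=0 & n_dq8<=0]: n=470 (212 cases / 258 controls)
#>     * stratum 2 [n_dq25<=0 & n_dq8>=1]: n=215 (124 cases / 91 controls)
#>   split n_dq8 <= 0  (chi2 = 15.68, p = 7.49e-05)
#>     split n_dq25 <= 1  (chi2 = 11.57, p = 0.000672)
#>       * stratum 3 [...]: n=1073 (949 cases / 124 controls)
#>       * stratum 4 [...]: n=279 (266 cases / 13 controls)
#>     * stratum 5 [n_dq25>=1 & n_dq8>=1]: n=148 (117 cases / 31 controls)
max(tree_split_pvalues(tree))
#> [1] 0.002261857
```

All four accepted splits are significant below 0.003; the terminal nodes
are exactly the DQ2.5 homozygotes (279), DQ2.5/DQ8 heterozygotes (148),
DQ2.5/non-DQ8 heterozygotes (1073), DQ8 carriers (215) and
non-DQ2.5/non-DQ8 samples (470).

The full synthetic analysis lives in `analysis/01_simulate.R` …
`analysis/06_joint_models.R` (run them in order from the repository root;
outputs land in `results/`). On the default cohort the adjusted scan plus
clumping recovers all four planted loci as clump indices:

```
4 independent loci identified:
  index_snp      index_p n_secondary
1  snp01510 2.608848e-15           8
2  snp01130 2.019673e-12           6
3  snp00390 4.054965e-10           5
4  snp00770 3.076067e-09           6
planted loci recovered as indices (or r2>=0.8 block-mates): 4/4
```

with estimated per-allele odds ratios (1.68–1.99) bracketing the planted
values (1.7–2.2), and all four remaining significant in the joint
stratum-adjusted model.

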