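---
title: "Methods: diabetes-stratified GWAS meta-analysis and interaction testing for eGFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diabetes-stratified GWAS meta-analysis and interaction testing for eGFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratgwas)
```

## The problem

Kidney function is routinely quantified as the estimated glomerular
filtration rate (eGFR), derived from serum creatinine through the 2009
CKD-EPI creatinine equation, winsorized at 15 and 200 ml/min/1.73 m^2 and
analysed on the natural-log scale. Genetic effects on eGFR may differ
between individuals with diabetes mellitus (DM) and without (noDM): a
variant can act in one stratum only, or more strongly in one stratum. This
package implements the full analysis chain for detecting such
differences from DM/noDM-stratified GWAS summary statistics:
per-study stratified GWAS, per-stratum fixed-effect meta-analysis with
double genomic control, the cross-stratum difference test and the 2-df
joint test, two identification designs, locus definition, approximate
conditional analysis, credible-set fine-mapping with rule-based gene
prioritization, and stratified genetic-risk-score (GRS) evaluation —
exercised end to end on a synthetic multi-study cohort generator.

## Statistical model

**Stratified GWAS.** Within each study and stratum, log eGFR is regressed
on allele dosage under an additive model, adjusted for age and sex
(`run_stratified_gwas()`). Covariates are projected out of both phenotype
and genotypes, so per-variant estimates equal the full OLS fit exactly.

**Meta-analysis.** Per stratum, study estimates are combined by
fixed-effect inverse-variance weighting: beta = sum(w_s b_s)/sum(w_s),
w_s = 1/se_s^2, se = (sum w_s)^{-1/2}, with Cochran's Q and
I^2 = max(0, (Q - df)/Q) for heterogeneity. Genomic control uses
lambda = median((b/se)^2)/0.455 (0.4549364 internally); when lambda > 1
standard errors are inflated by sqrt(lambda). Deflation (lambda < 1) is
reported but never applied — the usual convention, chosen because the
correction targets inflation from stratification. "Double GC" applies the
correction per study and again to the meta-analysis result.

**Difference test.** For each variant,

$$Z_\mathrm{diff} = \frac{\hat\beta_\mathrm{DM} - \hat\beta_\mathrm{noDM}}
{\sqrt{se_\mathrm{DM}^2 + se_\mathrm{noDM}^2
 - 2\,r\,se_\mathrm{DM}\,se_\mathrm{noDM}}}$$

where r is the Spearman correlation between the DM and noDM effect
estimates across all analysed variants (`estimate_r_diab()`), capturing
the shared polygenic component that correlates the two estimate vectors
even though the strata are disjoint samples. With r = 0 the statistic is
the standard two-sample z-test; the test is equivalent to a
SNP-by-DM-status interaction test. This genome-wide r is deliberately a
single constant (estimated once per data set); a per-chromosome estimate
changes results negligibly at realistic r and complicates reproducibility.

**Joint test.** $C = z_\mathrm{DM}^2 + z_\mathrm{noDM}^2$ referred to
chi-square with 2 df; its survival function is exactly $e^{-C/2}$, which
the implementation reproduces to 1e-12 on the log scale. The joint test
finds loci associated in either or both strata; it pays a df penalty
against the better single-stratum test when the signal is confined to one
stratum.

**Designs.** Two identification designs are orchestrated by
`run_design()`: discovery+replication (genome-wide screen at p < 5e-8 in
stage 1, one-sided replication in stage 2 at 0.05/k for k followed
variants, direction fixed by the stage-1 difference sign) and the combined
design (same thresholds applied to the pooled stage 1+2 meta-analysis).
The overall+difference approach screens on the IVW-reconstructed
all-individuals association and assesses the difference at 0.05/k among
the k overall-significant candidates. All threshold comparisons are strict
and evaluated on the -log10 scale, so p-values such as 1e-188 never
underflow the logic.

**Loci and conditional analysis.** Genome-wide significant variants are
clumped by iterative greedy selection: the most significant remaining
variant seeds a region that absorbs significant variants within 500 kb of
its borders until stable, the region is padded by 250 kb, and the
procedure repeats — equivalent to single-linkage clustering at 500 kb,
which the test suite verifies against an independently coded brute-force
merger. "Within 500 kb" is read inclusively (<= 500,000 bp), which
guarantees non-overlap of padded loci for separations above 500 kb.
Secondary signals are found by approximate conditional analysis from
summary statistics: X'X is rebuilt from LD-reference correlations and
per-variant dosage variances, X'y from the marginal betas, and the
phenotypic sum of squares from the median per-variant implied variance;
joint estimates then follow the normal equations with t-based p-values
whose degrees of freedom match an individual-level OLS fit. When the
reference panel is the analysis cohort itself the reconstruction is exact
(the acceptance suite demonstrates agreement to 1e-6); with an external
panel it is approximate in the usual summary-statistics sense. Targets
with LD R^2 >= 0.9 against the conditioning set are reported as not
estimable rather than returned with unstable estimates.

**Fine-mapping.** Per signal, the Wakefield normal-approximation Bayes
factor is computed from (beta, se) with a N(0, W^2) effect prior,
W = 0.05 log-eGFR units by default — roughly twice the largest plausible
common-variant eGFR effect, a weakly informative choice; all credible-set
properties (normalization, minimality) are prior-agnostic. PPAs normalize
the ABFs within a signal under a single-causal-variant assumption;
multi-signal loci are conditioned first. The 99% credible set is the
minimal descending-PPA prefix reaching 0.99 (a 1e-9 tolerance guards
exact sums like 0.6 + 0.3 + 0.09 against float rounding). Gene
prioritization flags a gene when a credible variant with PPA >= 5% has
CADD PHRED >= 15 for that gene or is a kidney eQTL/sQTL at FDR < 5%, or
when a listed kidney-disease monogene overlaps the locus. Which stratum's
statistics feed fine-mapping is the identifying test's stronger stratum;
the choice is logged per locus by the workflow driver.

**GRS.** Scores are weighted sums of eGFR-lowering alleles; weights are
magnitudes aligned per scheme (overall, DM-specific, noDM-specific, or
hybrid: stratum-specific at difference variants, overall elsewhere).
Association uses untransformed eGFR (ml/min/1.73 m^2) with age/sex
adjustment; the score is standardized by the full evaluation-sample SD so
per-SD effects are comparable across strata (the alternative,
stratum-wise SDs, would conflate weight performance with stratum
frequency differences). Explained variance is incremental R^2 over the
covariate-only model — chosen over marginal R^2 because covariates are
deliberately prognostic here. The evaluation refuses to run on the cohort
that estimated the weights unless explicitly overridden, enforcing the
stage separation that makes the reported R^2 honest.

## The synthetic cohort generator

`sim_config()`/`simulate_panel()` emulate multi-study DM/noDM-stratified
cohorts:

- **Genotypes**: biallelic dosages from a block-diagonal Gaussian copula —
  latent AR(1) normals (adjacent correlation `ld_rho`, default 0.4, blocks
  of 20 variants) thresholded through binomial(2, MAF) quantiles. This
  yields correct marginal frequencies and tunable local LD; it does not
  emulate long-range LD, recombination hotspots, or allele-frequency
  spectra.
- **Strata**: DM drawn independently of genotype at prevalence 0.12
  (within the 10-15% range typical of adult population studies); a config
  switch makes DM genotype-dependent for robustness checks.
- **Phenotype**: log eGFR = intercept (log 90, with a mild age trend) +
  stratum-specific planted effects + a shared polygenic background scaled
  to a fraction `polygenic_h2_shared` (default 0.15) of phenotypic
  variance + Gaussian noise (SD 0.25 log units, matching the dispersion of
  adult eGFR). Serum creatinine is then obtained by inverting the CKD-EPI
  equation at the target eGFR, and the stored phenotype is the winsorized
  log of the equation applied to that creatinine — exactly the convention
  applied to real cohorts, so planted effects live on the analysed scale.
- **Imputation Info** is Beta(18, 2) per variant and exercises only the
  QC filter; dosage noise itself is not modelled.
- The shared background is what makes the cross-stratum effect
  correlation positive, the mechanism the difference test's r term
  corrects for.
- `variant_seed` pins the variant metadata (ids, positions, alleles,
  population MAFs) independently of the genotype seed, so independent
  stage-2 cohorts share the stage-1 genome.

What passing tests on this generator do **not** show: robustness to
imputation error, relatedness and mixed-model corrections (out of scope;
plain OLS only), trans-ancestry structure, X-chromosome inheritance, or
real allele-frequency/LD architecture.

## Numerical choices

- All p-values are computed on the log scale (`pnorm(..., log.p = TRUE)`,
  `pchisq(..., log.p = TRUE)`) and carried with a -log10 companion column,
  so magnitudes far below double precision remain usable.
- Boundary semantics mirror strict-inequality wording throughout:
  Info < 0.6 excluded (0.6 kept), MAF < 0.001 excluded, MAC < 400
  excluded, study presence <= 50% excluded, identification at p
  strictly below 5e-8.
- Lead-variant ties break by larger |Z|, then smaller (chr, pos).
- Monomorphic variants are excluded from GWAS output with a record of
  their ids; zero-variance GRS and undefined correlations raise errors
  rather than propagate NaN.
- Degenerate difference-test denominators (|r| -> 1 with equal ses) raise
  a numeric-guard error.

## Problem sizes

The test and acceptance runs use desk-scale versions of the study
conditions: null calibration on 10,000 independent variants in a
4,000-individual cohort (DM prevalence 0.12); power recovery for a planted
DM-only effect (MAF 0.30, beta 0.06 log units) over 500 replicates of
2,000 individuals; conditional-analysis validation on an 8-variant LD
block in ~5,000 individuals; clumping validated on 200 random significance
patterns. The workflow drivers under `analysis/` simulate three studies of
6,000 individuals and 600 variants with planted shared, DM-only and
noDM-only effects (-0.04, -0.07, -0.035 log units). Planted effects are
several-fold larger than the per-allele effects reported for biobank-scale
consortia because the simulated samples are ~100x smaller; the qualitative
behavior (which tests identify which architecture) is what the workflow
demonstrates.

## Known limitations

- GC correction at desk scale over-corrects when a sizeable polygenic
  background is spread over few variants (every variant is then truly
  associated); the workflow drivers show this honestly in their printed
  lambdas.
- The overall association is reconstructed by IVW over the two strata;
  consortium practice may instead use an external all-individuals GWAS,
  and `run_design()` accepts such statistics via the LOG10P_OVR column of
  its input.
- The conditional reconstruction assumes a homogeneous sample behind the
  marginal statistics; applying it across heterogeneous meta-analyses
  inherits the usual caveats of summary-statistics conditioning.
- Fine-mapping assumes one causal variant per signal; multi-causal
  architectures require conditioning to split signals first.
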