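---
title: "Methods: principal-component CSF biomarker phenotypes, GWAS and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: principal-component CSF biomarker phenotypes, GWAS and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`pcgwas` implements a multivariate genetic analysis of six cerebrospinal
fluid (CSF) analytes — tau, pTau, A&beta;42, NfL, YKL-40 and neurogranin —
measured in elderly participants of a two-study design spanning the clinical
range from cognitively unimpaired through mild cognitive impairment (MCI) to
Alzheimer's disease (AD) dementia. The analysis has four stages:

1. **Phenotype construction.** Within each study the raw analyte
   concentrations are replaced by rank-based inverse normal scores; missing
   cells are completed by regularized iterative PCA with a cross-validated
   component count; a varimax-rotated PCA of the completed matrix yields
   five component scores interpreted as tau pathology/degeneration (PC1),
   A&beta; pathology (PC2), injury/inflammation (PC3), non-AD inflammation
   (PC4) and non-AD synaptic functioning (PC5).
2. **Association.** Each SNP passing QC (MAF &ge; 0.01 in every study,
   imputation R&sup2; strictly above 0.30, Hardy-Weinberg p &ge; 5e-6) is
   regressed on each component score under main, sex-stratified and
   SNP-by-sex interaction linear models, per study, and combined by
   inverse-variance fixed-effect meta-analysis.
3. **Gene aggregation.** Per-SNP chi-squares are summed within positionally
   annotated genes and referred to a weighted-chi-square null whose weights
   are the eigenvalues of the local SNP correlation matrix.
4. **Mediation.** Independent genome-wide significant SNPs (greedy clumping
   at r&sup2; &le; 0.6, p &lt; 5e-8) enter a structural model in which the
   SNP acts on a latent ordinal AD outcome directly and through the five
   component scores.

# The latent-AD model and its standardization

Diagnosis (control &lt; MCI &lt; AD) is treated as a coarsening of a
continuous latent AD variable with thresholds at &minus;1.47 and 0.40 SD.
We estimate this model by maximum-likelihood ordinal probit in the
latent-response formulation (residual variance fixed at 1) rather than by a
weighted least squares fit of polychoric moments. With a single
three-category indicator the two estimands coincide — the "item factor
analysis" of one ordinal item *is* an ordinal probit — and maximum
likelihood composes cleanly with the nonparametric bootstrap we use for
mediation inference; the difference is only in how the fit is weighted.

Because probit coefficients live on the residual-SD scale, every reported
coefficient is re-standardized to the latent-AD SD scale:
\[
\beta_{std} = \beta_{probit}\,\mathrm{sd}(x)\big/\sqrt{\operatorname{var}(\hat\eta) + 1},
\]
with $\hat\eta$ the fitted linear predictor; thresholds are divided by the
same factor. Per-allele SNP effects omit the $\mathrm{sd}(x)$ factor. This
convention makes products of a linear SNP&rarr;PC path (per allele, in
score SD) and a probit PC&rarr;AD path (per score unit, in latent SD)
well-defined per-allele mediated effects. The mediation product always uses
the per-raw-unit b-path, so the decomposition identity
$\text{total} = \sum_j a_j b_j + \text{direct}$ holds to machine precision
whatever the empirical score SD.

The proportion mediated, joint/total, is reported only when the joint and
total effects share a sign; otherwise it is undefined and reported as `NA`
(printed to two decimals when defined). Standard errors come from a seeded
nonparametric bootstrap over individuals (default B = 1000): products of
linear and probit coefficients are noticeably skewed at realistic effect
sizes, which a delta-method normal approximation handles poorly, while the
Wald test applied to a product of two near-null paths is conservative —
this is also why the sex-moderation rule (flag when any pathway-difference
product has p &lt; 0.05) holds its nominal level well below 5&times;5%
despite testing five pathways.

# Component construction choices

**Inverse normal transform.** Blom's offset (3/8) with average ranks for
ties, applied within study: the transform is cited generically in this
literature and the offset choice changes nothing qualitatively; within-study
application removes additive assay offsets and any monotone marginal
distortion between platforms.

**Cross-validation granularity.** The component count is chosen by deleting
one *observed cell* at a time and predicting it from the rest; deleting
whole rows would leave nothing to predict a held-out sample with, since the
imputation model is a matrix-completion model. Each per-cell refit is
warm-started from the full-data completion and accelerated by Steffensen
extrapolation of the one-dimensional EM map for the held-out cell: the plain
EM refill converges only linearly, at a rate set by the panel's high
communalities (~0.94-0.99), whereas the extrapolated fixed point is reached
in a handful of sweeps and is the same fixed point. `maxCells` optionally
subsamples the held-out cells; the test suite uses 800 cells at n = 1158
(the error-curve gap between four and five components is an order of
magnitude larger than the subsampling noise), the operation's default is the
full leave-one-observation-out sweep.

**Regularization.** Each retained eigenvalue is shrunk toward the mean
residual eigenvalue ($\sigma^2$ scaled by the `regularization` argument;
1 = full shrinkage, 0 = plain iterative PCA). Convergence tolerance 1e-6 on
imputed cells, 1000-iteration cap, with the last delta carried in the error
on non-convergence. An all-missing column is refused by name.

**Rotation and alignment.** Principal axes of the correlation matrix are
rotated by varimax with Kaiser normalization, implemented as cyclic pairwise
planar rotations with the per-pair angle maximized in closed form. The
pairwise form is deliberate: two exactly equally strong components (equal
eigenvalues) leave the pre-rotation basis arbitrary and put gradient-based
varimax updates on a saddle where they stall, while the closed-form pairwise
angle steps off it — the two-block worked example in the tests exercises
precisely this case, and a non-degenerate panel is cross-checked against
`stats::varimax`. Loadings are structure coefficients. Components are
ordered and sign-aligned by anchor markers — tau, A&beta;, NfL, YKL-40,
neurogranin for PC1..PC5 — each canonical component claiming the unassigned
column loading strongest on its anchor, ties broken by variance explained;
without anchors, variance-explained order with the dominant marker positive.

**Scores.** Regression weights $R^{-1}\Lambda$ applied to column-standardized
data, rescaled to unit theoretical SD under the training correlation matrix;
Bartlett-style weights sit behind `method = "bartlett"`. A fitted `PCModel`
is frozen: applying it to a new cohort reuses the stored weights and never
refits, which is how replication cohorts are scored.

**Group comparison.** The full transform-impute-rotate pipeline is fitted
per group, the second group's components are aligned to the first by maximal
absolute Tucker congruence, and absolute loading differences below 0.04 are
flagged "indifferent". Two cautions, both visible in the tests: the 0.04
bound is a large-sample notion — at ~550 samples per group the *null* max
loading difference is typically 0.05-0.08 from rotation noise alone, so the
indifference property is tested at 3000 per group — and varimax partially
reabsorbs a cross-loading contrast planted in the generating factor model,
so recovered fitted differences are compared against the pipeline's own
large-n population mapping rather than the planted value.

# Association engine

Dosages (not hard calls) enter the regression; hard calls (rounded dosages)
are used only for the Hardy-Weinberg filter, which is computed per study on
all samples — the source analyses do not restrict HWE to controls — with a
chi-square test, adequate at the 5e-6 threshold for study sizes near 500.
For X-chromosome SNPs the HWE counts use females only, since hemizygous
males coded 0/2 would fake disequilibrium; male X dosages are coded 0/2
throughout so one allele copy matches the female homozygote scale, with no
further variance adjustment.

The per-SNP OLS is computed by residualizing outcome and dosages on the
covariate design once (Frisch-Waugh), which reproduces full-design
estimates, standard errors and t-based p-values exactly (verified against a
normal-equations oracle to 1e-8) while scanning thousands of SNPs in
vectorized algebra. Stratified models drop the sex covariate inside each
stratum; the interaction model reports the dosage-by-sex (female = 1)
product term — the female-minus-male per-allele difference, and exactly
$\beta_F - \beta_M$ without covariates. SNPs whose residualized design is
numerically collinear (e.g. monomorphic within a stratum) are dropped with a
logged reason rather than emitted as NA rows; the report layer prints the
absence.

# Meta-analysis, gene tests, multiplicity

Cross-study combination is inverse-variance fixed-effect; the
DerSimonian-Laird random-effects variant is available for sensitivity
analysis (no method is prescribed for it in this literature; DL is the
standard default). A sample-size-weighted meta is deliberately not
implemented. Allele harmonization flips swapped effect alleles, resolves
strand-flipped representations, and drops strand-ambiguous (A/T, C/G)
variants with frequency in (0.4, 0.6); the synthetic generator simply never
produces ambiguous pairs, so simulated pipelines lose nothing.

The gene test is the SNP-wise mean model: the sum of per-SNP 1-df
chi-squares referred to $\sum_i \lambda_i \chi^2_1$ with $\lambda$ the
eigenvalues of the SNP correlation matrix. LD is estimated from the analysis
cohort's own dosages — self-contained and asymptotically equivalent to
reference-panel LD for this purpose. The tail probability uses Imhof-style
numerical inversion (tolerance 1e-9) with two guards: exactly equal weights
reduce to a scaled chi-square in closed form, and the extreme tail
(p &lt; 1e-12, where the oscillatory integral loses relative accuracy) falls
back to gamma moment matching. Annotation windows default to 0 kb on
1-based inclusive intervals. The gene-wise threshold is literal Bonferroni,
`alpha / nGenes`; for 19,511 genes that is 2.56e-6 (a slightly stricter
published threshold of 2.3e-6 presumably reflects a different effective gene
count; the operation implements the formula).

Remaining constants: 5e-8 genome-wide, 1e-6 suggestive, 0.05/6 for the six
mediation/direct pathways, 0.05/5 for the five sex-mean tests, clumping at
r&sup2; &le; 0.6, Manhattan/QQ p-values winsorized at 1e-10.

# What the synthetic cohort does and does not emulate

The generator's defaults are the study conditions: two studies totalling
973-1158 elderly participants; the canonical 6&times;5 loading structure
with uniquenesses of one minus the implied communalities (floored at 0.005);
female mean shifts of &minus;0.40 SD on PC3 and +0.21 SD on PC5;
PC&rarr;latent-AD coefficients (0.41, &minus;0.34, 0.40, 0, 0) with
thresholds (&minus;1.47, 0.40), giving roughly 7% controls / 58% MCI / 35%
AD margins; Hardy-Weinberg genotypes at configurable MAF; planted main and
female-only per-allele SNP effects; 10% missingness, completely at random
(the mechanism is not documented for the source data; MCAR is the neutral
choice); a sign-preserving monotone distortion `exp(x/2)` of the raw marker
scale, giving the strong right skew typical of CSF analyte concentrations;
additive per-study assay offsets (removed again by the per-study INT);
imputation-quality values Uniform(0.3, 1) so QC filtering has work to do;
age ~ N(72, 6) and five standard-normal ancestry components.

Not emulated: realistic LD beyond optional exchangeable-correlation blocks
(a Gaussian copula with Hardy-Weinberg margins, used by the gene-level null
tests), haplotype structure, population stratification, informative
missingness, and selection effects linking diagnosis to recruitment.
Passing tests therefore demonstrate correctness of the estimators under the
stated generative model, not robustness to confounding that the real data
may contain.

One generative subtlety deserves emphasis. In the generator, diagnosis is a
*descendant* of the component scores. Adjusting a sex-difference regression
for the dummies of a descendant of both sex and the outcome attenuates the
sex coefficient (a collider-type adjustment) — with the default
PC&rarr;latent coefficients the PC3 shift shrinks by roughly 10-15%. In the
real-data design the diagnosis adjustment is motivated by diagnosis acting
upstream, through recruitment and case mix. The sex-mean recovery
simulations therefore set the PC&rarr;diagnosis coefficients to zero, making
the dummies pure covariates, which is the condition under which the planted
marginal shift is the estimand the adjusted regression targets; the
full-cohort default keeps the nonzero coefficients.

The latent index in `simulateDiagnosis` scales its residual to
$1 - \widehat{\operatorname{var}}(\eta)$ (floored at 0.02) so the index has
unit variance and the thresholds keep their SD interpretation; degenerate
thresholds like (&minus;1e6, 1e6) are allowed and give an all-MCI cohort.

# Problem sizes in the test suite

Simulation-based checks run at deliberately chosen sizes: GWAS recovery at
the genotyped sample size (n = 973, 100 replicates), sex-mean recovery at
the phenotyped size (n = 1158, 10 seeds in the suite and 80 in the
acceptance script), latent-AD recovery at the male
stratum size (n = 601), component-count CV at n = 1158 with 800 held-out
cells, null calibration with 5000 SNPs at n = 500, gene-level null with 400
five-SNP LD blocks, and bootstrap coverage with 100 replicates of n = 300
at B = 100. These sizes put Monte-Carlo noise well inside each check's
tolerance while keeping the full suite comfortably re-runnable.

# Known limitations

* The mediation model assumes no unmeasured confounding of the PC&rarr;AD
  paths and linearity of all structural equations; neither is testable here.
* In-sample LD makes gene-level p-values mildly optimistic for genes whose
  SNPs were themselves selected by association in the same sample; the
  pipeline only tests annotation-defined genes, which avoids the worst of
  this.
* The ordinal probit replaces a weighted least squares polychoric fit; at
  three categories and these sample sizes the estimands agree, but exact
  numerical equality with WLSMV output should not be expected.
* The moderated-mediation reporting rule is a screening device, not a test
  with controlled family-wise error.
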