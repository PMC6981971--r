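---
title: "Methods: spectral indices, indirect selection, and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral indices, indirect selection, and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `spectralGS`, its
assumptions, the tunable parameters, the synthetic-data generator, and the
design decisions taken where conventions genuinely differ between software
packages.

## Spectral reflectance indices

Five indices are computed from discrete band reflectances (fractions in
[0, 1]) at exact wavelengths: NDRE-1 (800/700 nm), NDRE-2 (800/750), NDVI
(800/680), NWI-1 (970/900) as normalized differences
$(R_a - R_b)/(R_a + R_b)$, and the simple ratio SR $= R_{900}/R_{680}$.
Band matching is by exact nm key: handheld multispectral radiometers carry
discrete filters, and nearest-band interpolation would silently mask a
mislabelled column, so a missing band is an error naming the index and the
band. Zero denominators raise errors rather than propagating NaN.

Growth stages are normalized to `Hd` (heading), `Gf1` (early grain fill /
milk) and `Gf2` (late grain fill / soft dough). Stage means for report
tables are arithmetic means over non-missing plots per stage pooled across
environments; per-environment-then-averaged means are available via
`stageMeans(by_environment = TRUE)` since the granularity is a genuine
convention choice. Stage-to-stage changes are reported as
$100\,(\bar{x}_{to} - \bar{x}_{from})/|\bar{x}_{from}|$, so a negative
value is a decrease and a negative-valued index (NWI-1) rising from −0.08
to −0.06 is a +25% increase.

## Augmented-design adjustment

Trials follow the augmented design: replicated check cultivars in every
block, un-replicated test entries. Two adjustment modes:

* **BLUE, single environment.** Response = mean + block + genotype, all
  fixed, fitted by least squares. The genotype factor spans checks and
  entries jointly, which is the same column space as the check/entry
  two-part decomposition (check-vs-entry indicator plus within-checks
  identifier). Block effects are estimable only through the checks; a
  block without checks raises an error. Reported entry values use a
  **sum-to-zero block convention** (entry contrasts are invariant to this
  choice; the intercept anchor is not, and no convention is universal
  across software, so ours is stated here and tested).
* **BLUP, combined across environments.** Genotype, check identity,
  environment, genotype x environment, check x environment and blocks
  nested in environments are random; the 1-df check-vs-entry separator is
  kept **fixed** because a two-level random effect is not meaningfully
  estimable. Entries and checks carry dummy pooled levels in each other's
  identity factors. Entry values are mean + genotype BLUP, i.e. shrunk
  toward the grand mean (the shrinkage property is tested). Fitting is
  REML via `lme4::lmer`.

Variance components for heritability come from the same random model.
Broad-sense heritability on an entry-mean basis is
$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GEI}/n + \sigma^2_\varepsilon/(nr)},$$
with $n$ environments and $r$ replications per environment ($r = 1$ for
un-replicated entries; the package computes $r$ as the mean plots per
entry per environment). With un-replicated entries, $\sigma^2_{GEI}$ and
$\sigma^2_\varepsilon$ are separable only through the checks; note that
$H^2$ itself remains consistent under this confounding because the
formula's denominator depends on them only through
$\sigma^2_{GEI}/n + \sigma^2_\varepsilon/n$ when $r = 1$.

Numerical choices: the REML optimizer is bobyqa with `rhoend = 1e-13`,
tight enough that on balanced two-way data the estimates coincide with the
closed-form ANOVA expected-mean-squares solution to 1e-6 (tested against
that oracle). The nested-block term is included automatically only when
checks are present (`blocks = "auto"`): in an augmented layout blocks are
estimable through checks, whereas in a plainly replicated balanced trial
the block label is a bare replicate index and including it would move the
estimator off the classical ANOVA solution. Estimates are deterministic
given the data and invariant to record order.

## Indirect-selection statistics

Genetic covariance between an index x and yield y uses the pairwise-sums
identity
$\mathrm{Cov}_g(x,y) = [\sigma^2_G(x{+}y) - \sigma^2_G(x) - \sigma^2_G(y)]/2$,
with each component from the univariate REML engine on the same plots.
This reuses one well-tested engine instead of a bivariate REML and is
exact for balanced data. The genetic correlation is
$r_G = \mathrm{Cov}_g / \sqrt{\sigma^2_{gx}\sigma^2_{gy}}$ — with the
square root in the denominator (the Falconer definition; a variance
product without the root is not bounded by 1). Sampling error can push
$|r_G|$ past 1, in which case the value is clipped with a warning flag;
a genotypic variance estimated at its zero boundary leaves the correlation
undefined and the report row is flagged rather than aborting the table.

The selection quantities are $R = \sqrt{H^2_x}\,\sigma_{gx}$ (response to
selection), $CR = \sqrt{H^2_x}\, r_G\, \sigma_{gy}$ (correlated response
of yield to selection on the index; sign follows $r_G$), and
$RE = CR_x / R_y$ (relative efficiency; RE > 1 means indirect selection
wins). The identity $RE = r_G \sqrt{H^2_x / H^2_y}$ is an algebraic
consequence and is asserted to 1e-12 on every report row. Phenotypic
correlations are Pearson correlations of per-environment BLUEs pooled
across environments (the computation granularity is another unstated
convention; pooling is the default, per-environment reporting is
available from the same building blocks).

## Genomic prediction

RRBLUP: $y = X\beta + Mu + \varepsilon$, $u \sim N(0, \sigma^2_u I)$ over
column-centered dosages $M$ (the infinitesimal model with equal marker
variance). The ratio $\lambda = \sigma^2_\varepsilon/\sigma^2_u$ is
estimated by REML profiled through the eigendecomposition of $MM'$
projected off the fixed effects (a coarse log-grid bracket followed by
Brent refinement to 1e-10; the restricted likelihood in the single ratio
is well behaved). Marker effects then have the closed form
$u = M'(MM' + \lambda I)^{-1}(y - X\hat\beta)$ with $\hat\beta$ by
generalized least squares; this equals the primal ridge solution
$(M'M + \lambda I)^{-1}M'(y - X\hat\beta)$ and the GBLUP genetic values
under the $MM'$ kernel, both asserted to 1e-8 in tests. Dosage coding
{0,1,2} versus {−1,0,1} is irrelevant after centering (tested to 1e-10);
the package codes toward the minor allele because that keeps MAF
bookkeeping trivial.

Cross-validation partitions lines into k near-equal seeded folds (sizes
differ by at most one; 456 lines in 5 folds gives 92/91/91/91/91).
$\lambda$ is estimated once on the full training data and reused per fold
— the standard practice — with `per_fold_lambda = TRUE` for strictness.
Accuracy is the Pearson correlation of observed adjusted means with GEBVs
per fold, averaged; a fold with constant observations is excluded with a
warning. Independent validation fits on the full training panel and
predicts a separate panel over the markers shared by id.

Secondary-trait fixed effects: the indices are measured on the test plots
in the emulated design, so prediction **requires** test-line covariate
values by default; `covariate_policy = "train_mean"` substitutes training
means, which is an extrapolation that shifts all predictions equally and
is only useful to preserve the marker-based ranking. Which growth stage's
values serve as covariates is configurable; the default is the per-trait
adjusted means pooled across stages.

QC and imputation: markers are kept at MAF strictly above the threshold
(default 0.05). Mean imputation fills marker means (fractional dosages
allowed). LD-kNN imputation selects, per target marker, the `l = 30` most
correlated markers (r² over pairwise-complete calls), then imputes each
missing cell from the `k = 10` donor lines nearest by matching distance on
those markers, inverse-distance weighted; both defaults follow common
GBS-imputation practice and are configurable. Ties break deterministically
by line order.

## Population structure

Roger's distance: per biallelic locus with counted-allele frequencies
$p, q$ in the two panels, $d_j = \sqrt{\tfrac12[(p-q)^2 + ((1-p)-(1-q))^2]}
= |p - q|$, averaged over loci; line-to-line distance is the same
definition with single-line panels. The distance is in [0, 1], symmetric,
and satisfies the triangle inequality (tested exhaustively on toy sets).
Both panels must carry the same per-marker allele orientation — the
same-genotyping-pipeline assumption; `readGenotypeMatrix(orient = FALSE)`
supports keeping an externally fixed orientation. Marker PCA centers by
marker mean; unit-variance scaling is off by default and exposed, since
reference implementations differ.

## The synthetic-data generator

No field data ship with the package; `simScenario()` defines the study
conditions and `generateScenario()` builds complete bundles. Defaults
emulate a winter-wheat diversity panel: 456 fully homozygous (DH-style)
lines, 11,089 independent biallelic markers with founder MAF in
[0.1, 0.5] (post-QC panels guarantee realized MAF > 0.05), four
environments of augmented blocks with two replicated checks per block,
yield heritability 0.19 with $\sigma^2_{GEI} = 0.5\,\sigma^2_G$, and five
indices whose heritabilities (0.16–0.63) and genetic correlations with
yield (−0.42 to 0.66) span the low-to-moderate range typical of such
trials, including a negatively correlated water index. Trait means and
genotypic SDs are on natural scales (yield 6 ± 0.5 t/ha; NDVI 0.80 ±
0.05; NWI-1 −0.07 ± 0.015; SR 15.8 ± 2.0) — values chosen once as
field-realistic.

Architecture: yield marker effects are i.i.d. normal; each index's
effects are $r_G u_y + \sqrt{1 - r_G^2}\, u'$, giving the target genetic
correlation in expectation. Residual noise per trait is solved from the
target entry-mean $H^2$ given $\sigma^2_{GEI}$ and the environment count.
Traits measured on the same plot share a standard-normal plot-noise
component mixed at `r_E` (default 0.6, signed like the trait's $r_G$):
index and yield residuals on one plot share micro-environment in the
field, and without this the phenotypic correlations would be implausibly
near zero whenever yield heritability is low. The field layout
(entry-to-block randomization) derives only from the scenario seed, so
all traits share their plots; one global seed governs every draw through
a fixed splitting scheme.

Test panels draw founder frequencies from a `relatedness`-weighted mixture
of the training pool and an independent pool; the `independent_like`
preset builds a closer, more heritable DH-like panel (relatedness 0.9,
yield $H^2$ 0.55) and a more distant, less heritable F5-like panel
(relatedness 0.6, $H^2$ 0.14), which together reproduce the qualitative
orderings the analysis is about: accuracy higher for the related panel,
and higher with correlated spectral covariates than without.

What the generator does **not** emulate: linkage disequilibrium between
markers (loci are independent; LD-kNN imputation is exercised on
hand-built correlated fixtures instead), genotype-by-environment
correlation structure between traits, spatial field trends beyond block
effects, and radiometric physics — reflectance tables are built by
inverting the normalized-difference formulas from simulated index values
around fixed canopy-typical anchor bands (R800 = 0.50, R900 = 0.45) plus
Gaussian band noise (SD 0.01, an invented but harmless figure), with
index values clamped to ±0.95 so bands stay inside (0, 1); SR is implied
rather than targeted because it shares R680 with NDVI. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to LD, spatial autocorrelation, or sensor artefacts.

## Problem sizes used in tests

The test and acceptance suites run the estimators at sizes chosen to make
Monte-Carlo error small relative to the tolerances while keeping a full
run around two minutes: heritability/genetic-correlation recovery uses
500-entry, four-environment panels over 20 seeds (tolerances ±0.05 on
$H^2$, ±0.1 on $r_G$); null cross-validation uses 120 lines x 200 markers
over 20 seeds; relatedness and fixed-effect orderings use 250-entry
training panels with 500 markers over 10 seeds. Marker counts enter these
checks only through the genetic architecture, so they are kept moderate.
A replicate whose genotypic variance is estimated at the zero boundary
(which legitimately happens at yield-like heritability) leaves $r_G$
undefined for that draw and is excluded from seed averages.

## Known limitations

* Genetic covariance by pairwise sums is exact for balanced data but can
  be noisy in severely unbalanced layouts; a bivariate REML would be the
  upgrade path.
* The BLUP-combined model pools all environments; no factor-analytic or
  heterogeneous-variance G×E structure.
* Spatial adjustment (row-column, AR1) is out of scope; adjustment is
  block-based only.
* Strand flips between separately genotyped panels are not detected;
  marker intersection assumes one genotyping pipeline.
* `H^2` at the zero boundary of $\sigma^2_G$ yields degenerate (constant)
  BLUPs; downstream consumers should drop such traits, as the pipeline
  driver does for covariates.
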