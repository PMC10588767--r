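---
title: "Statistical methods in AgeProteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in AgeProteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AgeProteomics)
```

This vignette documents the statistical model behind each stage of the
package, the synthetic-data generator and its default parameters, and the
numerical choices in the custom mixed-model code. For a quick tour of the
API, see the README; for reference detail on any function, see its help
page.

## Study design

The design the package targets is a cross-sectional multiplexed
proteomics study of aging: $4g$ mice ($g$ per age × sex cell; by default
$g = 5$, so 20 mice across young/old × F/M), each contributing the same
set of tissues (10 by default). Each tissue is measured in two TMT
11-plex batches: 10 labels carry one mouse each and the 11th carries a
pooled *bridge* sample common to both batches. The bridge anchors the two
batches on a common scale; the TMT tag and the batch are technical
factors whose contributions the package models explicitly.

## Quantification

For tissue $t$ and batch $b$, let $I_{pis}$ be the reported intensity of
peptide $p$ of protein $i$ in sample $s$. Quantification proceeds in
three steps (`computeScalingFactors()`, `rollupProteins()`,
`bridgeNormalize()`, or all at once via `quantifyTissue()`):

1. **Sample scaling factors.** $\theta_s = T_s / \max_{s' \in b(s)}
   T_{s'}$, where $T_s$ is the total peptide intensity of sample $s$ and
   the maximum runs over samples of the same batch, bridge included. This
   equalizes loading within a batch without changing the batch's scale.
2. **Protein rollup.** $y_{is} = \sum_{p \in i} I_{pis} / \theta_s$ —
   the scaled sum over the protein's peptides.
3. **Bridge normalization.**
   $\tilde y_{is} = \log_2\!\big((y_{is} + 1) / (y_{i,\mathrm{bridge}(s)} + 1)\big)$,
   the log2 ratio to the bridge sample of the same batch. The +1
   pseudo-count keeps proteins with a zero sum finite; for intensities of
   realistic magnitude ($\gg 1$) its effect is $O(1/y)$ and negligible,
   but it does mean the chain is exactly scale-free only up to that
   perturbation.

Quality control then:

* removes proteins observed in only one batch
  (`filterSingleBatch()`; the batch-observation mask is kept in the
  object's metadata),
* flags outlier samples whose score on either of the first two principal
  components is more than `kMad = 5` median absolute deviations from the
  median (`detectOutlierSamples()`); flagging is advisory by default and
  removal is opt-in,
* regresses the batch indicator out of each protein
  (`regressOutBatch()`), storing the result as the `"adjusted"` assay
  used for correlation-based analyses.

The result is a `ProteinQuant`, a `SummarizedExperiment` subclass with
assays `log2ratio` and `adjusted`, sample annotation in `colData`, and
tissue/QC information in `metadata`.

## Per-tissue differential abundance

Within one tissue, each protein is fit by ordinary least squares:

$$\tilde y_{is} = \beta_0 + \beta_{\mathrm{age}}\,\mathrm{old}_s +
\beta_{\mathrm{sex}}\,\mathrm{female}_s +
\beta_{\mathrm{int}}\,\mathrm{old}_s\,\mathrm{female}_s +
\beta_{\mathrm{batch}}\,\mathrm{batch2}_s + \varepsilon_{is}.$$

Each effect (age, sex, age-by-sex) is tested by a partial F-test of the
nested model without that term; with a single coefficient this equals the
squared t-statistic. All proteins share the same design matrix, so the
fits are vectorized through a single QR decomposition. P-values are
adjusted by Benjamini–Hochberg separately per tissue × effect-type
family (`proteinEffects()`, `bhFdr()`).

## Cross-tissue mixed models

Stacking tissues (`stackTissues()`) gives each protein up to
$20 \times 10$ observations with repeated measures per mouse. Consistent
effects are estimated by a linear mixed model with a random mouse
intercept:

$$y = X\beta + Z u + \varepsilon,\quad u \sim N(0, \tau^2 I),\quad
\varepsilon \sim N(0, \sigma^2 I),$$

with fixed effects for age, sex, tissue, and a global batch indicator.
The package ships its own fitter (`lmmFit()`) for this one-random-factor
case:

* The REML criterion is profiled down to a one-dimensional problem in
  $\lambda = \tau^2/\sigma^2$ and minimized by `optimize()` over
  $\log\lambda \in [-15, 15]$, with $\lambda = 0$ always evaluated as a
  boundary candidate so singular fits are found exactly.
* Because mice are independent, $(I + \lambda Z Z^\top)^{-1}$ is block
  diagonal and each block has the closed form
  $I - \frac{\lambda}{1 + \lambda n_g} \mathbf{1}\mathbf{1}^\top$, so no
  large matrix is ever inverted.
* Degrees of freedom are Satterthwaite approximations
  (`lmmSatterthwaite()`): the variance of
  $\widehat{\mathrm{var}}(c^\top\hat\beta)$ is obtained by the delta
  method from the asymptotic covariance of $(\hat\sigma^2, \hat\tau^2)$,
  which is $2 H^{-1}$ with $H$ the Hessian of the REML $-2\ell$. The
  Hessian is computed by finite differences, using a forward-biased
  stencil in $\tau^2$ when the estimate is at the $\tau^2 = 0$ boundary.

Tissue-specificity (age-by-tissue, sex-by-tissue) is tested by a
maximum-likelihood likelihood-ratio test between the models with and
without the interaction (`lmmLRT()`, `testEffectByTissue()`); aliased
interactions (a protein observed in too few tissue × group combinations)
are reported as skipped rather than silently dropped. The test suite
verifies `lmmFit()` against `lme4`/`lmerTest` as an independent oracle;
`lme4` is *not* used in this code path at run time.

## Variance decomposition

For proteins observed in every tissue, `varianceDecomposition()` fits
(REML, via `lme4`, reusing a single fitted template across proteins with
`refit()` for speed)

$$y = \beta_0 + \beta_{\mathrm{age}}\,\mathrm{old} +
\beta_{\mathrm{sex}}\,\mathrm{female} + u_{\mathrm{mouse}} +
u_{\mathrm{tag}} + u_{\mathrm{batch}} + \varepsilon$$

and reports each factor's share
$\mathrm{VarP}_f = \tau^2_f / (\tau^2_{\mathrm{mouse}} +
\tau^2_{\mathrm{tag}} + \tau^2_{\mathrm{batch}} + \sigma^2)$; the four
shares sum to one by construction. BLUPs of every random-effect level are
returned with ±1.96 conditional-SD predictive intervals.

## Protein-complex co-abundance

Given a complex catalog (GMT format, `readComplexCatalog()`), members are
intersected with the quantified proteins and complexes with fewer than 4
observed members are dropped (`filterComplexes()`).

* **Cohesiveness** of a complex in a set of samples is the median over
  members of each member's median pairwise Pearson correlation with the
  other members (`complexCohesiveness()`), computed on the
  batch-adjusted assay. It is 1 exactly for perfectly co-varying members,
  is invariant to affine rescaling of any member, and zero-variance
  members are excluded with a recorded reason.
* **Complex-wide abundance effects** are tested with
  `y ~ old + female + (1|mouse) + (1|protein)` over all member × sample
  observations (`testComplexAbundanceEffect()`, via `lmerTest`).
* **Cohesiveness change** between the two levels of a factor (age or
  sex) is tested by a paired t-test across member pairs of the
  within-level pairwise correlations (`testCohesivenessChange()`).
  Levels are compared in alphabetical order, so for age the effect is
  young minus old. Complexes whose correlation pairs are degenerate
  (zero variance of differences) are flagged, not tested.
* **Per-pair permutation tests** (`permutationTestPair()`) test the
  change in correlation magnitude for a single member pair with the
  statistic $T = \big||r_1| - |r_2|\big|$ under permutations of the
  factor labels *stratified by the other factor* (sex strata when
  testing age, and vice versa), preserving group counts within each
  stratum. When the number of distinct arrangements is at most the
  requested `P`, all arrangements are enumerated and the p-value is
  exact; otherwise `P` Monte-Carlo draws are used with the add-one
  estimator $(1 + \#\{T^\ast \ge T\})/(1 + P)$, so a reported p-value
  is never 0. Per-pair seeds are derived from the pair identity, making
  results independent of execution order.

BH adjustment for the abundance and cohesiveness-change families is done
across tissues by `adjustComplexFamilies()`.

## The synthetic-data generator

`simulateStudy()` generates the full study with known ground truth; its
defaults are the study conditions, not a convenience setting. Per protein
and tissue, the latent log2 abundance is

$$y = \beta_{\mathrm{age}}\,\mathrm{old} +
\beta_{\mathrm{sex}}\,\mathrm{female} + u_{\mathrm{mouse}} + u_{\mathrm{tag}}
+ u_{\mathrm{batch}} + \lambda_{\mathrm{age}} f + \varepsilon$$

where a fraction `propAffected = 0.1` of protein × tissue pairs receives
$\beta_{\mathrm{age}} = \pm 0.6$ (and independently for sex), complexes
co-vary through a shared latent factor $f$ with age-dependent loading
(`complexLoading = c(young = 0.5, old = 0.5)`), and the variance
components default to `mouseSd = 0.1`, `tagSd = 0.1`, `batchSd = 0.2`,
`residualSd = 0.2`. The residual default is calibrated against the whole
chain, not just the latent layer: with the peptide-level noise,
efficiency spread, and detection settings above, the remaining layers
contribute about 0.22 SD to a quantified protein's per-observation noise,
so `residualSd = 0.2` puts the total at 0.30 and the planted effects at a
signal-to-noise ratio of 2 — comfortably but not trivially detectable.

The peptide layer then makes the observations realistic: each protein
gets 2–8 peptides with lognormal baseline (`baselineMean = 12` on the
log2 scale) and per-peptide ionization efficiency
(`peptideEfficiencySd = 0.5`), multiplicative measurement noise
(`peptideNoiseSd = 0.3`), and binomial peptide detection
(`detectProb = 0.8`). Bridge intensities are generated from the pooled
mean of all mice. Ground truth (`truth_effects.tsv`) records every
planted coefficient, enabling end-to-end recovery checks.

Everything is seeded: `simConfig(seed = )` fixes the generator,
`runConfig(seed = )` fixes the pipeline, and independent substreams are
derived for each stage so adding a tissue or stage does not shift the
random numbers of another.

## Numerical and scope notes

* The profiled-REML fitter handles exactly one random intercept factor;
  models with crossed random effects (variance decomposition, complex
  abundance) use `lme4`/`lmerTest` directly.
* Satterthwaite degrees of freedom use a finite-difference Hessian;
  agreement with `lmerTest` is to about $10^{-3}$ in p-values in the
  test suite, which is far below any decision threshold used here.
* `lme4` occasionally emits max-gradient convergence warnings around
  $2\times10^{-3}$ (tolerance $2\times10^{-3}$) on boundary-ish
  proteins in the variance decomposition; estimates are unaffected at
  the reported precision.
* The permutation test's add-one estimator is conservative by design;
  exact enumeration removes that conservatism whenever feasible.
* Outlier flagging with only 20 samples per tissue is intentionally
  advisory: MAD-based thresholds are unstable at this size and removal
  is left to the analyst (`removeOutliers` argument of
  `quantifyTissue()`).
* The generator does not simulate peptide-level interference
  (co-isolation), missing-not-at-random intensity dependence, or
  protein degradation products; its missingness is uniform per peptide.
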