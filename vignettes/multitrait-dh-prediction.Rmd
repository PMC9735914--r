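---
title: "Multi-trait genomic prediction for doubled-haploid maize breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction for doubled-haploid maize breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices
behind them, and what the simulation-based tests do and do not establish.

## The breeding problem

Doubled-haploid (DH) technology turns the gametes of a biparental maize
cross into fully homozygous lines within two seasons. That speed creates a
selection bottleneck: with 100 candidate lines per heterotic pool there
are 100 × 100 = 10,000 possible hybrids, far more than any field budget
can test. Two shortcuts are on the table: (i) phenotype the *haploid*
progenitors a season earlier and select indirectly, and (ii) predict the
performance of unphenotyped DH lines from genome-wide markers, possibly
borrowing strength from genetically correlated traits, environments and
the haploid population. This package implements the full analytical
chain needed to evaluate both: population simulation, marker QC and
relationship matrices, univariate and multi-trait genomic mixed models,
CV2 cross-validation with a genetic-accuracy estimator and the corrected
resampled t-test, and deterministic selection-response theory.

## The core model

Everything Bayesian in the package is a special case of

$$ Y = \mathbf{1}\mu' + u + \varepsilon, \qquad
   \mathrm{vec}(u) \sim N(0,\, G_0 \otimes K), \qquad
   \mathrm{vec}(\varepsilon) \sim N(0,\, R_0 \otimes I), $$

where $Y$ is lines × "traits" (actual traits, environments, or the
DH/haploid populations treated as trait pairs), $K$ is the VanRaden
genomic relationship matrix, and $G_0$, $R_0$ are the genetic and
residual covariance matrices across the trait dimension. The covariance
structures are selectable: diagonal (D), unstructured (UN), or
factor-analytic (FA, $G_0 = \Lambda\Lambda' + \mathrm{diag}(\psi)$).
`fit_multitrait()` fits any combination by Gibbs sampling;
`fit_bivariate_dh_hap()` is literally the two-trait case (the test suite
asserts bit-level identity), and the multi-environment models are the
same sampler with one column per environment.

Genetic and phenotypic correlations between the DH and haploid
populations come from the 2 × 2 fit:

$$ r_G = \frac{\sigma_{G(D,H)}}{\sqrt{\sigma^2_{G(D)}\sigma^2_{G(H)}}},
\qquad
 r_P = \frac{\sigma_{G(D,H)} + \sigma_{\varepsilon(D,H)}}
 {\sqrt{(\sigma^2_{G(D)}+\sigma^2_{\varepsilon(D)})
        (\sigma^2_{G(H)}+\sigma^2_{\varepsilon(H)})}}, $$

with $\sigma_{\varepsilon(D,H)} = 0$ because the two populations grow in
separate, independently randomized blocks.

### Sampler internals

One eigendecomposition of $K$ per fit; inside each sweep the
genetic-effect update simultaneously diagonalizes $(G_0, R_0)$ via a
Cholesky-plus-eigen transform, so the conditional posterior factorizes
over lines *and* traits and each sweep is a handful of dense matrix
products — no per-line loops. Missing cells of $Y$ are sampled each sweep
(data augmentation), which makes CV2 prediction a by-product of fitting,
mirroring how practitioners use BGLR. Updates: intercepts (flat prior),
genetic effects (as above), $G_0$ and $R_0$ from inverse-Wishart (UN),
scaled-inverse-$\chi^2$ (D) or a factor-analytic sub-sampler (FA).

Priors are weakly informative and BGLR-like: inverse-Wishart with
$\nu = t + 2$ and scale $0.5\,\mathrm{diag}(\widehat{\mathrm{var}}(Y))$
for UN blocks, scaled-inverse-$\chi^2(\mathrm{df}=5)$ with scale half the
trait variance for diagonal variances, flat intercepts, and independent
normals with geometrically increasing column precision ($2^{c-1}$) on FA
loadings. The genetic/residual split is initialized from per-trait
spectral REML rather than a flat 50:50 split: the Gibbs chain forgets the
initialization either way, but the warm start shortens burn-in when a
trait is strongly heritable or nearly noise.

Two numerical behaviors worth knowing:

* **Attenuation at low information.** In a biparental panel at $n
  \approx 187$ and $h^2 \approx 0.2$, the genetic and residual
  covariances are weakly separated and the posterior mean of $r_G$
  shrinks toward zero (estimates of a generating 0.7 typically land
  around 0.55–0.65). This is a property of the posterior, not a sampler
  defect: the posterior mean tracks the direct marginal-likelihood MLE in
  large-$n$ checks, and the plug-in and posterior-mean-of-ratio
  estimators agree. Recovery tests therefore use a median-absolute-error
  criterion rather than per-fit unbiasedness.
* **Non-identifiability at $K = I$.** With an identity kinship the
  phenotypic covariance is $(\sigma^2_g + \sigma^2_e) I$ — the split is
  not identified and only predictions (which depend on the fitted ratio)
  are testable. Variance-recovery tests always use structured kinships.

### Univariate models

`fit_gblup()` is spectral REML: after projecting out the intercept and
eigendecomposing the training kinship once, the restricted likelihood is
profiled over $\delta = \sigma^2_e/\sigma^2_g$ and maximized by bounded
golden-section search (tolerance $10^{-10}$ on $\log\delta$); breeding
values for unphenotyped lines are conditional means through the
cross-block of $K$. A brute-force grid search of the restricted
likelihood on a six-line toy pins the optimum to $10^{-3}$ relative in
the tests. `fit_plot_model()` (block fixed, genotype random, REML via
lme4) turns plot records into the shrunken line BLUPs that feed the
prediction models — the package's default adjusted phenotype, with plot
means available by just skipping this step.

`fit_bayesb()` is the classical marker-effect mixture: each effect is
zero with probability $\pi$ (default 0.95) or normal with a
marker-specific scaled-inverse-$\chi^2$ variance (df 5, scale solved so
the included markers explain half the phenotypic variance a priori);
indicator sampled with the effect integrated out; the single-site loop is
compiled (Rcpp) and driven by R's RNG so chains are seed-reproducible.
With $\pi = 0$ it collapses to an all-markers normal-effects sampler,
cross-checked in the tests against an independent reference
implementation.

### The factor model

For the 26–35-trait panels a full UN fit is impractical (and with eight
or more trait-environment columns even the unstructured bivariate-style
models converge poorly — the reason the FA structures exist).
`fit_factor_model()` fits

$$ Y = \mathbf{1}\mu' + F\Lambda' + U_r + E, $$

where the $k$ (default 8) factor columns split into genetic and residual
parts, $f_c \sim N(0,\, h_c K + (1-h_c) I)$ with $h_c$ sampled on a
discrete grid (0–0.9 by 0.1, MegaLMM-style), $U_r$ holds trait-specific
genetic effects $u_{rj} \sim N(0, \sigma^2_{gj}K)$, and $E$ is white
noise. The idiosyncratic genetic term matters: without it a trait with no
shared structure would receive no genetic prediction at all, whereas the
intended behavior (asserted in the tests) is collapse to per-trait
GBLUP-like accuracy. Loadings carry the same geometric column shrinkage
as the FA structure. This is an honest simplification of the published
high-dimensional factor regression packages — fixed $k$, no nonlinear
extensions — and the package claims qualitative, not bit-level, agreement
with them.

Predictions of breeding values use the *genetic* component
(`U_gen`: shrunken genetic factor parts plus $U_r$), never the full
fitted value: secondary traits measured on the same plots share
non-genetic variation with the focal traits, and letting the residual
factor leak into predictions would inflate apparent accuracy.

## Cross-validation and inference

CV2 masking: in the single-environment scheme a random half of the lines
loses all focal-trait cells per repeat (secondary traits stay complete);
in the multi-environment scheme 20% of lines are masked independently per
environment, and the same masks serve every model compared. Accuracy is
`cor(y, a-hat)` pooled over masked cells in multi-environment runs.
In the single-environment trait-assisted setting the focal and secondary
traits share plots, so accuracy is instead the estimated genetic
correlation between predictions and observations times
$\sqrt{\hat h^2_{\hat u}}$: the correlation comes from a short bivariate
Gibbs fit on the test lines, while $\hat h^2_{\hat u}$ comes from
spectral REML — the REML choice avoids the inverse-Wishart scale putting
a floor under the residual variance of an almost-noiseless predictor,
which would cap the estimator visibly below 1 for a perfect predictor.

Model comparisons across repeated CV runs use the corrected resampled
t-test: $t = \bar d / \sqrt{(1/J + n_{test}/n_{train})\, s^2_d}$ with
$J - 1$ df. The ratio is 1 for the 50:50 scheme and 0.25 for 80:20,
derived from the schemes. Calibration is checked empirically: under an
exchangeable null with overlapping folds the corrected test rejects at
2–4% (nominal 5%) while the naive resampled t-test rejects at over 60%.
No multiple-testing correction is applied across traits (per-trait
verdicts are reported as such); a Benjamini–Hochberg adjustment is one
`p.adjust()` call away for users who want it.

## The synthetic study

The generator's defaults are the study conditions: 187 lines, 10
chromosomes of 150 cM with 132 evenly spaced markers each (~1,320 total,
matching the chip scale), 10% of lines derived after 3 extra selfing
generations (the real pedigree was unrecorded; these two knobs are free),
haploids carrying exactly their DH line's genome, and phenotypes drawn
from the Kronecker model above. Meiosis is Haldane — Poisson crossover
counts, no interference — the simplest model consistent with the long
parental blocks the graphical genotypes show. Trait panels for the
prediction benchmarks use a single shared genetic factor (loadings drawn
so pairwise $r_G \in [0.45, 0.8]$), secondary-trait heritabilities in
[0.3, 0.6], focal-trait heritabilities in [0.15, 0.4], a common
residual plot factor with share 0.2, and DH/haploid genetic correlation
0.7 for the augmentation experiment — numbers chosen once from the
published trait summaries. Block effects are fixed draws per
(environment, block) with SD 0.25.

What the simulator does *not* emulate: genotyping error, segregation
distortion, inducer-genome carryover, linkage-disequilibrium decay within
parental haplotypes beyond what meiosis creates, non-Gaussian trait
distributions, and genotype-by-environment structure beyond what $G_0$
encodes. Passing tests therefore demonstrate internal consistency of the
methods under their own assumptions and the qualitative reproduction of
the study's findings — not that real stalk-quality data would show the
same per-trait accuracies.

## Problem sizes and chains

Defaults follow common practice for these models (20,000 iterations,
5,000 burn-in, thinning 5). The tests and the acceptance script run
deliberately smaller problems — chains of 800–1,500 sweeps after
REML-warm starts, 18 focal + 8 secondary traits instead of 18 + 17, and
J = 20 CV repeats as in the study — sizes chosen so the whole analysis
re-runs comfortably on a laptop while leaving every qualitative
conclusion intact. Short-chain accuracy estimation (800/300, thin 2 for
the bivariate accuracy fits) was checked against longer chains on pilot
data; posterior means move by less than Monte Carlo noise.

## Known limitations

* $r_G$ estimates attenuate toward zero at low heritability in panels of
  this size; credible intervals (via `genetic_correlation_posterior()`)
  are wide there and should be reported alongside point estimates.
* The factor model's $k$ is fixed, not inferred; the column-shrinkage
  prior makes over-specifying $k$ cheap, but severely under-specifying it
  merges factors.
* The QC boundary convention (strict inequalities; boundary values fail)
  follows the chip-filter wording; datasets filtered under a
  boundary-passes convention can differ by a handful of markers.
* `derive_haploid_population()` encodes the genetically forced identity
  assumption — a haploid carries exactly its DH line's gamete genome.
  Real haploid genotypes were not available to verify it, and any
  inducer-genome retention would violate it.
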