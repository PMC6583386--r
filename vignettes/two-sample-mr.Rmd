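---
title: "Two-sample Mendelian randomization with summaryMR: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with summaryMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summaryMR)
```

# The problem

Observational associations between circulating inflammatory biomarkers
(C-reactive protein, interleukin-6 pathway proteins) and psychiatric
disease are prone to reverse causation and confounding. Mendelian
randomization (MR) sidesteps both by using genetic variants as
instrumental variables: because genotypes are fixed at conception, a
variant that raises a biomarker provides a quasi-randomized contrast for
the biomarker's downstream effect. In the *two-sample* design the
variant–biomarker associations ($\hat\beta_{Xj}, \sigma_{Xj}$) and the
variant–disease associations ($\hat\beta_{Yj}, \sigma_{Yj}$) come from
separate, non-overlapping GWAS samples, and the whole analysis runs on
published summary statistics.

summaryMR implements that analysis end to end: reading and harmonizing
summary tables, five complementary estimators, weak-instrument
(attenuation) statistics with a SIMEX correction, heterogeneity /
influence / leave-one-out diagnostics, a product-of-coefficients
mediation calculation, and a generator of synthetic summary statistics
with known truth so every method can be validated against a ground
truth.

All effects are handled on natural-log scales: biomarker exposures in
ln-units, disease outcomes as ln-odds-ratios. A pooled estimate
$\hat\theta$ (ln-OR per ln-unit) is reported alongside the odds ratio
per 2-fold increment of the biomarker,
$$\mathrm{OR}_{2\times} = \exp(\hat\theta \cdot \ln 2),$$
i.e. the per-ln-unit odds ratio raised to the power $\ln 2$; confidence
bounds map through the same strictly monotone transform.

# Harmonization

`harmonize()` aligns the outcome table to the exposure's effect
alleles. Swapped alleles flip the sign of $\hat\beta_{Yj}$; alleles
reported on the opposite strand are complemented before comparison.
Palindromic variants (A/T, C/G) cannot be strand-resolved from allele
labels, so they are oriented — or dropped — using allele frequencies.

The default policy (`drop_ambiguous`) drops a palindromic variant when
its effect-allele frequency is missing or lies within 0.08 of 0.5 in
either table (i.e. in 0.42–0.58), and orients the remainder by
frequency. The 0.08 band is the conventional compromise in two-sample
MR pipelines: wide enough that sampling noise in the frequencies of two
different studies rarely crosses 0.5, narrow enough to retain common
variants. `infer_by_eaf` (orient whenever both frequencies exist) and
`keep` (trust the printed strands) are available for sensitivity
analyses. Every exclusion is recorded with a reason; nothing is dropped
silently. Only biallelic single-base variants are accepted — indels and
multi-allelic records fail validation, and identifiers are never
auto-corrected.

# Estimators

Per variant, the Wald ratio is
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ with first-order
standard error $\sigma_{Yj} / |\hat\beta_{Xj}|$. This SE treats
$\hat\beta_{Xj}$ as known — the "no measurement error" (NOME)
convention — and defines the weights $w_j$ used everywhere downstream.

**IVW.** $\hat\theta_{IVW} = \sum w_j \hat\theta_j / \sum w_j$,
algebraically identical to weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin. The fixed-effects SE is
$(\sum w_j)^{-1/2}$; the multiplicative random-effects model (the
package default) multiplies it by $\sqrt{\max(1, Q/(L-1))}$, where $Q$
is the Cochran statistic, so heterogeneity can only widen the interval.
The floor at 1 is deliberate: an overdispersion estimate below 1 is
sampling noise, and letting it deflate the SE would make the
fixed-effects model anti-conservative exactly when it looks best.

**Correlated instruments.** When instruments sit in partial LD, plain
IVW double-counts shared information. `mrIvwCorrelated()` fits the
generalized weighted regression through the origin with covariance
$\Omega = D\,\rho\,D$, $D = \mathrm{diag}(\sigma_{Yj})$:
$\hat\theta = (x^{\top}\Omega^{-1}x)^{-1} x^{\top}\Omega^{-1}y$. With
$\rho = I$ it reduces exactly to fixed-effects IVW (a test asserts
agreement to 1e-10). $\Omega$ is factorized by Cholesky; a failure or a
relative pivot below machine tolerance is reported as a conditioning
error with the advice to prune near-duplicate instruments rather than
silently regularizing.

**Weighted median.** Ratios are sorted and placed at the cumulative
midpoints $s_j = \sum_{k \le j} w'_k - w'_j/2$ of their normalized
weights; the estimate interpolates the ordered ratios at $s = 0.5$
(clamping to an extreme ratio in the degenerate single-dominant-weight
limit). It is consistent while valid instruments carry more than half
the weight. No closed-form SE exists, so the package uses a parametric
bootstrap — each ratio redrawn from $N(\hat\theta_j, se_j^2)$ with
weights held fixed, 1000 replicates by default, seed mandatory.

**MR-Egger.** Weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ *with* an intercept, after recoding each variant so
its exposure effect is non-negative (flipping the outcome effect in
tandem). The orientation step is what makes the intercept
interpretable: it estimates the average directional pleiotropic effect,
and is exactly zero whenever $\hat\beta_{Yj} = \theta\hat\beta_{Xj}$
for all $j$. Under the InSIDE assumption (instrument strength
independent of direct effects) the slope remains consistent even when
all instruments are pleiotropic. Fixed effects holds the residual
variance at 1; multiplicative random effects scales both SEs by
$\sqrt{\max(1, Q'/(L-2))}$.

P-values use the standard normal throughout; intervals are fixed at
95% ($z = 1.96$). Fold-scale ORs are rounded to 2 decimals only in the
flat report tables, never internally.

# Weak instruments: attenuation and SIMEX

The NOME convention is never exactly true. Sampling error in
$\hat\beta_{Xj}$ behaves like classical measurement error in a
regression covariate and attenuates estimates toward the null.
`attenuationStats()` reports two summaries:

* $\bar F = \frac{1}{L}\sum \hat\beta_{Xj}^2/\sigma_{Xj}^2$, with the
  expected retained fraction of the IVW estimate $\bar F/(\bar F + 1)$,
  as a percentage;
* $I^2_{GX} = \max\!\big(0, (Q_{GX} - (L-1))/Q_{GX}\big) \times 100$,
  where $Q_{GX}$ is the Cochran-type statistic of the exposure
  associations with weights $\sigma_{Xj}^{-2}$ — the expected fraction
  of the Egger slope retained. The $\sigma_{Xj}^{-2}$ weighting is
  the default; an outcome-weighted variant sits behind the `qWeights`
  flag. Negative excess heterogeneity is truncated at zero so both
  statistics honor their $[0, 100]$ contract.

`simexEgger()` corrects Egger by simulation extrapolation: for each
multiplier $\lambda \in \{0, 0.5, 1, 1.5, 2\}$ (the standard grid) it
adds synthetic noise $\sqrt{\lambda}\,\sigma_{Xj}\,\varepsilon$ to the
exposure associations over 1000 replicates, averages the refitted
coefficients, fits a quadratic in $\lambda$ and extrapolates to
$\lambda = -1$, the zero-measurement-error state. For the standard
errors the package uses the simulation-extrapolation difference method:
the model-based variance minus the between-replicate variance,
extrapolated alongside the coefficients and floored at zero. This is
the established variance construction for SIMEX and has the right
limiting behavior — with vanishing $\sigma_{Xj}$ every pseudo-dataset
coincides with the data and the corrected fit collapses onto the naive
one (asserted to 1e-8 in the tests). The correction is deterministic
given its seed.

# Diagnostics

`cochranQ()` refers $Q = \sum w_j(\hat\theta_j - \hat\theta_{IVW})^2$
to $\chi^2_{L-1}$; excess heterogeneity is the classic signal of
pleiotropy. `influenceScan()` computes leverage, studentized deleted
residuals and Cook's distance under the weighted-regression form of IVW
(origin regression) or Egger, flagging a variant when
$|t_j| > 3$ or $D_j > 4/L$ — the conventional cutoffs in the
regression-diagnostics literature; both thresholds are configurable and
stored with the report so every flag is reproducible from the metrics.
The diagnostics are obtained from base R's `lm`/`hatvalues`/`rstudent`/
`cooks.distance` on the exact weighted fit, so hat values sum to the
model dimension (1 for IVW, 2 for Egger) by construction. A fit whose
weighted residual sum of squares is at rounding level is treated as
exact: studentizing numerical zeros would manufacture spurious flags.

`leaveOneOut()` re-runs any subset of {IVW, Egger, weighted median}
once per excluded variant. The weighted-median bootstrap reuses the
same seed in every row, so rows differ only by the exclusion — the
quantity of interest — and an estimator failure on a reduced set is
recorded in the row rather than aborting the scan.

# Mediation

For an exposure believed to act on the outcome through a measured
mediator (e.g. IL-6 receptor signaling acting on schizophrenia risk
through CRP), `mediationAnalysis()` combines three MR estimates: the
exposure→mediator effect $a$, the mediator→outcome effect $b$ and the
total exposure→outcome effect $c$. The indirect effect is the product
$ab$ — the expected outcome effect under full mediation — reported also
as $\exp(ab \ln 2)$, and the proportion mediated is $ab/c$ as a
percentage.

Because the three estimates come from non-overlapping summary datasets,
covariances are taken as zero. The delta-method SE of $ab$ is
$\sqrt{b^2 se_a^2 + a^2 se_b^2}$. For the proportion, the default is
Monte-Carlo propagation (100000 independent normal draws, percentile
interval, seed mandatory): the ratio's delta interval degrades badly
when $c$ is imprecise, which is the common case. The Monte-Carlo
interval collapses onto the delta interval as the input SEs shrink (a
tested property). With $c = 0$ the proportion is undefined; the
indirect effect is still returned, with a warning.

# The synthetic-data generator

`simulateTwoSample()` draws from the canonical two-sample data model:
$$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2), \qquad
  \hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2),$$
with independent noise on the two sides (non-overlapping samples) and
pleiotropic effects $\alpha_j$ drawn independently of $\gamma_j$, so
InSIDE holds by construction. Defaults emulate a biomarker–disease
analysis with 18 strong instruments: true exposure effects
$|N(0.1, 0.05^2)|$ (folded positive, so truth bookkeeping needs no
orientation step; signed effects are available via `signedGamma`),
minor-allele frequencies uniform on 0.1–0.5, standard errors
$(2n\,\mathrm{maf}(1-\mathrm{maf}))^{-1/2}$ for standardized traits
with $n = 50000$ on the exposure side and $n = 80000$ on the outcome
side, the latter doubled (`outcomeSeScale = 2`) to approximate the
precision loss of a case-control ln-OR relative to a continuous trait
at a balanced case fraction. These sizes give mean instrument F
statistics of several hundred — the strongly-instrumented regime of
published biomarker GWAS consortia. Optional LD is modeled as a single
equicorrelated noise block, returned alongside the tables as the true
LD matrix. Balanced pleiotropy draws $\alpha_j$ with mean 0,
directional with mean `alphaMean`.

`simulateMediationTriplet()` layers the mediation structure on top:
disjoint instrument sets for exposure and mediator, with the exposure's
total outcome effect equal to $a b + \text{direct}$, and the truth
(including the implied proportion mediated) recorded.

What the generator deliberately does *not* model: individual-level
genotypes, winner's curse in instrument selection, sample overlap
between the two GWAS, allele-coding errors, population stratification.
A method that passes the recovery tests here is validated against the
assumed data model, not against those additional real-data pathologies.

# Validation scale and numerical choices

The test-suite simulation studies use 500 repetitions for parameter
recovery (mean IVW within 3 Monte-Carlo SEs of the generating
$\theta = 0.2$ at $L = 18$; interval coverage required in
$[0.92, 0.975]$), 1000 repetitions for the null rejection rate
($0.05 \pm 0.02$), and 500 for Egger-intercept recovery under
directional pleiotropy (`alphaMean = 0.02`) — sizes at which the
binomial tolerance bands above are meaningful while the whole suite
runs in about a minute. The SIMEX limit is checked at three decreasing
exposure-error scales.

Other numerical decisions, in one place: tie-handling in the weighted
median follows sort order (ties in ratios are harmless because the
interpolant passes through both); LD matrices may be asymmetric only to
1e-6 (repaired by symmetrization) and non-PSD matrices are rejected
unless an explicit eigenvalue-clipping repair is requested; a zero
exposure effect is a degenerate instrument and a hard error in the
ratio step (the user should prune it, not have it silently dropped);
`se = 0` rows are rejected at read time; every stochastic routine takes
a mandatory seed, runs on a private RNG stream and leaves the caller's
RNG state untouched.

# A worked run

```{r example, eval = FALSE}
study <- simulateTwoSample(simulationConfig(theta = -0.15, seed = 42))
h <- harmonize(exposureTable(study), outcomeTable(study))
est <- mrRatio(h)
mrIvw(est)
mrMedian(est, seed = 1)
mrEgger(h)
attenuationStats(h)
cochranQ(est)
```

The same analysis runs from files and a single config through
`runAnalysis()`, which writes flat report tables (one fold-scale OR row
per method, Egger intercepts on the odds scale), the harmonization log,
scatter-ready per-variant data, diagnostics, and a manifest that makes
the run reproducible byte for byte.

# Known limitations

* The proportion-mediated interval assumes independent normal inputs;
  when $c/se_c \lesssim 2$ even the Monte-Carlo interval is wide and
  its percentile bounds should be read qualitatively.
* SIMEX relies on the quadratic extrapolant being adequate over the
  grid; with extremely weak instruments ($\bar F < 10$) the
  extrapolation itself is the dominant error source.
* The correlated-instrument estimator takes the LD matrix as known;
  estimation error in reference-panel LD is not propagated.
* No mode-based estimators, multivariable MR, Steiger filtering, or
  outlier removal-and-refit loops: the package covers the estimator
  families above and stops there.
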