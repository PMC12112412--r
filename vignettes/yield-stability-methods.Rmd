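---
title: "Methods: yield stability, model agreement, and sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield stability, model agreement, and sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldstab)
```

This vignette documents the statistical models the package implements,
the design decisions taken where the methodology was genuinely open, the
numerical conventions, and what the synthetic generators do and do not
emulate.

## The problem

Long-term field experiments (LTEs) are the reference instrument for
judging the *temporal stability* of agronomic management options, but
they are rare and test few options. A crop model calibrated on an LTE
can, in principle, extend the comparison to untested options — provided
it reproduces not just average yields but the stability *ranking* of
treatments. The package implements the full chain needed to test that:
stability measures per treatment, goodness-of-fit statistics for the
model itself, and concordance statistics between field-derived and
model-derived stability.

## Stability measures

All measures operate on a treatment × environment matrix of
replicate-averaged mean yields (Mg ha⁻¹). An *environment* is a year, or
a year × season combination for double-cropping systems; which one is a
data-preparation choice encoded in `environment_id`. Stability statistics
are computed on replicate-averaged treatment-year means rather than
replicate-level yields: the per-treatment environment counts (n = 7–8
years) in the source experiments correspond to years, not plots, and
replicate noise would otherwise contaminate the interannual variance that
the measures are about. `pivot_matrix()` does the averaging; users who
want replicate-level analysis can pass a panel whose replicates are
encoded as environments.

**Adjusted CV.** The plain CV confounds stability with yield level
because variance scales with the mean (Taylor's power law). Fitting
log₁₀(σ²) = a + b·log₁₀(Ȳ) across the treatments of one (dataset,
source) group and sliding each treatment's log-variance along that slope
to the common mean log-yield m̄ gives

aCVᵢ = (100/Ȳᵢ) · sqrt(10^(vᵢ + (2 − b)(mᵢ − m̄))).

Two exact identities pin the implementation down and are asserted in the
tests: at b = 2 the aCV equals the plain CV for every treatment, and any
treatment sitting at mᵢ = m̄ has aCV = CV for any b. Zero-variance
treatments have no representable log-variance; they abort the summary by
default and are dropped with a warning inside `stability_table()` rather
than floored, so a constant treatment cannot silently distort the Taylor
fit.

**Grouping of the Taylor fit.** The regression needs a set of treatments
to pool. The package fits one regression per (dataset, source)
combination — observed and predicted each get their own slope, pooling
season/density/residue levels within a crop. This matches how the
concordance comparisons are grouped (pooled "All" rows first) and keeps
the observed statistic independent of model output. It is configurable
by passing pre-grouped summaries to `fit_taylor()` directly. Note that
aCV values recomputed from *rounded* published means and SDs reproduce
published aCV columns only to about one percentage point; the bundled
rice summaries give a pooled observed slope b ≈ 0.99, and the 0-N
hot-dry-season row evaluates to 26.5% against a printed 27.1%.

**SYI.** `SYI = (mean − sd)/y_max` with the sample (n − 1) SD. `y_max`
is "the maximum yield in all years and treatments" *within the group
being compared*: `stability_table()` defaults to the per-source maximum
cell yield, so observed SYI is scaled by the observed maximum and
predicted SYI by the predicted maximum (back-solving the published rice
SYI columns supports per-source maxima: roughly 8.4 observed vs 8.0
predicted). When only summary moments are available, `y_max` must be
supplied.

**Finlay–Wilkinson.** Per-treatment OLS of yield on the environment mean
yield ωⱼ (column means of the matrix), unweighted — no weighting scheme
is part of the method definition here. On a complete matrix the mean of
the fitted slopes is exactly 1 (the regressor is the row-average of the
responses), a property asserted to 1e−10. Treatments observed in fewer
than 3 environments are skipped with a warning; a constant treatment is
reported as slope 0 with the constant as intercept.

## Model-evaluation statistics

`evaluate_pairs()` implements RMSE_a, the normalized RMSE_n =
100·RMSE_a/Ō, MAE, and Willmott's index

WI = 1 − Σ(Eᵢ−Oᵢ)² / Σ(|Eᵢ−Ō| + |Oᵢ−Ō|)²,

with the regression of predicted on observed (the convention that puts
observations on the x-axis of evaluation scatterplots). Because the MAE
is a mean of absolute values it cannot indicate the *direction* of
error; the signed mean bias mean(E − O) is reported as a separate column
so over/underestimation stays recoverable. The mean-difference test is
Welch's unpaired unequal-variance t-test by default, with a paired
option (`welch_t(..., paired = TRUE)`) for users who prefer treating the
series as matched pairs; the unpaired form is the default because the
two series' variances genuinely differ when a model compresses
interannual variability. The degenerate both-sides-constant case returns
p = 1 when the means agree, by convention.

## Concordance of stability measures

Lin's CCC with population (1/n) moment estimators:
CCC = 2s_xy/(s_x² + s_y² + (x̄−ȳ)²), r = s_xy/(s_x s_y), C_b = CCC/r.
The 1/n convention matters at the small n (3–12) typical of
treatment-wise comparisons; it is what reproduces the published
agreement cells from the bundled summaries at 2-decimal precision.
Pearson r is kept *signed* internally — C_b = CCC/r is then always in
(0, 1] — and reported alongside |r|, since published agreement tables
sometimes print the absolute correlation (the pearl-millet adjusted-CV
row is only internally consistent with a signed r ≈ −0.31 behind its
printed r = 0.32, CCC = −0.23, C_b = 0.72). Groups with fewer than three
pairs are skipped with a warning rather than producing meaningless
coefficients.

Concordance of Finlay–Wilkinson slopes requires per-year yields on both
sides; it is exercised end-to-end on synthetic panels
(`analysis/04_concordance.R`) because the bundled summaries hold only
means and SDs.

## Sensitivity analysis

The estimands are the classical variance-based indices
Sᵢ = Var{E(f(X)|xᵢ)}/Var{f(X)} and STᵢ = 1 − Var{E(f(X)|x₋ᵢ)}/Var{f(X)}.
They are estimated by Saltelli's A/B/AB scheme on a Sobol' base sample —
the Saltelli-2010 estimator for Sᵢ and the Jansen estimator for STᵢ,
chosen for their lower variance — rather than by Gaussian-process
emulation: at the problem sizes involved, direct Monte-Carlo estimation
of the same estimands is feasible, exactly reproducible, and free of an
emulator's approximation error. The 400-point LP-tau *design* stage is
still provided (`lp_tau_design()`) for parity with emulator-based
workflows. The correctness anchors are analytic: an additive
three-input model (all indices 1/3), the Ishigami function with its
closed-form variance decomposition, and a single-active-input model; the
acceptance tolerance of ±0.02 at n_base = 8192 reflects the Monte-Carlo
error at that sample size. Negative index estimates are reported as-is
so estimator bias stays visible.

The Sobol' generator uses the published Joe–Kuo direction numbers
(dimensions 2–50, 31-bit precision, Gray-code order) with the zero point
skipped, so the first point is the cube midpoint; a seeded
Cranley–Patterson rotation (mod-1 shift) makes replicate runs of
`saltelli_indices()` differ while retaining low discrepancy.

**Failed runs.** Crop simulators fail on some parameter combinations
(crop never matures). Failures are handled by `discard_failed()`
block-wise: one base row couples its A, B and all ABᵢ evaluations, and a
missing output anywhere in the block removes the whole block, keeping
the paired estimators consistent. More than 50% failures aborts, since
the surviving sample is then both small and strongly selection-biased.
Per-year analyses refit on each year's own surviving blocks (the
failure region may be year-dependent).

## Synthetic generators

`generate_lte_panel()` draws observed yields as
yᵢⱼ = βᵢ + αᵢωⱼ + εᵢⱼ with ωⱼ ~ N(env_mean, env_sd) and
sd(εᵢ) = sqrt(c·Ȳᵢᵇ); the predicted series shares ωⱼ but has its
deviations from the treatment mean multiplied by a shrinkage factor in
(0, 1] plus an independent noise term of the same shrunken scale, and an
optional level bias. This emulates the salient feature of the real
model-output panels — predictions less variable than observations —
without simulating any soil or plant process. Negative draws are
truncated at zero (zero is a valid crop-failure yield) rather than
resampled, keeping the moment structure analyzable; a truncation rate
above 10% warns, or errors in strict mode.

Two presets reproduce the study conditions of the source panels:
`sadore_millet` (12 treatments × 8 years, means 0.26–0.55 Mg ha⁻¹) and
`ndiaye_rice` (8 N-by-season cells × 8 years, 1.6–6.6 Mg ha⁻¹), with
treatment means set to the published observed means, the Taylor noise
law fitted to the published (mean, SD) pairs after setting aside a
common environment-effect variance (half the smallest published SD),
shrinkage set to the mean published SD ratio (capped at 1), and bias to
the mean published mean offset. The rice preset uses 8 environments for
all cells (the wet season has 7 in the source data; a rectangular panel
keeps the generator simple and changes no tested property). Preset
slopes are 1: the emulation targets the mean/SD structure, not the
published F–W ordering.

Two recovery properties calibrate trust in the whole chain: noise-free
panels return the configured F–W coefficients to 10 significant digits
(exact provided the slopes average 1 and intercepts average 0, since the
realized environment index is then the configured one), and the Taylor
exponent b* ∈ {1, 1.5, 2} is recovered within ±0.1 from 200-environment
panels *in the pure power-law configuration* (env_sd = 0). The latter
restriction is structural, not numerical: a shared environment effect
adds the same variance αᵢ²·env_sd² to every treatment, which flattens
the realized log-variance/log-mean slope below b*, so recovery of the
noise-law exponent is only well-posed when the interannual variance is
the power-law noise itself.

What the generator does **not** emulate: serial correlation between
years, treatment × year interactions beyond the F–W line, replicate
structure, non-Gaussian yield distributions, and any mechanistic
weather–yield link (the weather generator is entirely separate). Tests
passing on synthetic panels therefore certify the *statistical chain*,
not crop-model realism.

`toy_crop_model()` is a smooth response surface over five
phenology-flavored parameters with one deliberately centered product
term (`rue` × grain-fill response) that carries interaction-only
variance — so STᵢ − Sᵢ > 0.05 is detectable for that pair — a failure
region (total thermal-time demand above 1150 °Cd returns NA, about 15%
of the unit cube), and a deterministic year effect derived from the
context label. It is a test instrument, not a crop model.

`generate_weather()` produces sinusoidal temperature cycles with noise
and a seasonally modulated Bernoulli–gamma rainfall process whose
expected annual total equals the site preset (565 mm for Sadoré, 277 mm
for Ndiaye); rainy days are slightly cooler and dimmer. The Blackman
thermal-time rule is printed in its source only for temperatures below
the optimum; above the optimum this package caps the daily increment at
TOD − TBD (linear-with-plateau reading) and offers `above_tod = "zero"`
as the alternative, since a bilinear decline cannot be parameterized
from the available description.

## Numerical conventions and problem sizes

- Sample (n − 1) SDs everywhere in stability summaries; population (1/n)
  moments only inside Lin's CCC.
- All tabular I/O is comma-delimited UTF-8 with headers; missing yields
  are explicit NA, never 0.
- Deterministic ordering: paired series sort by (treatment, environment,
  replicate); matrices sort rows and columns by label.
- Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; nothing depends on global seed side-effects.
- Test problem sizes: Saltelli runs use n_base = 8192 for the
  closed-form anchors (Monte-Carlo error well under the 0.02 tolerance)
  and 1024–2048 for structural checks; recovery tests use 200
  environments and 50-seed replicate loops. These sizes keep the whole
  suite around two minutes on one core while leaving comfortable
  statistical margins.

## Known limitations

- The aCV's Taylor slope is estimated from few treatments (8–12 here);
  its sampling error propagates into every aCV value and is not
  quantified.
- `y_max` back-solved or supplied externally makes SYI values
  scale-dependent across groups; compare SYI only within one (dataset,
  source) group.
- The Sobol' generator covers 50 dimensions; larger parameter spaces
  need an extended direction-number table.
- Concordance point estimates carry no confidence intervals; at n = 3–4
  they are highly variable and should be read as descriptive.
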