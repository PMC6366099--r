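---
title: "Detecting gain of circadian rhythmicity with hierarchical Gaussian processes"
author: "LipidRhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gain of circadian rhythmicity with hierarchical Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipidRhythm)
```

## The problem

Chronic inflammatory disease can *re-wire* circadian physiology: serum
lipids — ceramides in particular — that show no daily rhythm in healthy
subjects can acquire a robust 24 h oscillation in rheumatoid arthritis.
Detecting this gain of rhythm from clinical serum sampling is statistically
awkward: each subject contributes only ~5 samples across one day, subjects
differ in their individual lipid trajectories, and the question is about a
rhythm *shared across subjects*, not about any one subject's wiggles.

LipidRhythm implements a hierarchical Gaussian-process (GP) model built for
exactly this design, together with a likelihood-ratio rhythmicity test, an
acrophase (peak-time) estimator, a gain/loss classifier across groups, a
simplified JTK-style nonparametric detector for balanced, evenly sampled
(animal) designs, and a synthetic-data generator that emulates the clinical
sampling scheme.

## The model

For one analyte in one group, let $y_{si}$ be the normalized concentration
of subject $s$ at time $t_{si}$ (hours). The model is

$$y_{si} = g(t_{si}) + f_s(t_{si}) + \varepsilon_{si},$$

with three independent components:

* **Shared rhythmic component** $g \sim \mathcal{GP}(0, k_p)$, common to
  all subjects, with the exp-sine-squared (periodic) kernel
  $k_p(t, t') = \sigma_p^2 \exp\{-2 \sin^2(\pi (t - t')/T)\,/\,\ell_p^2\}$
  and period fixed at $T = 24$ h. This component carries the hypothesis
  under test.
* **Subject deviation** $f_s \sim \mathcal{GP}(0, k_m)$, independent across
  subjects, with a Matérn 3/2 kernel
  $k_m(r) = \sigma_m^2 (1 + \sqrt{3} r/\ell_m) e^{-\sqrt{3} r/\ell_m}$,
  $r = |t - t'|$: smooth but aperiodic individual trajectories.
* **Noise** $\varepsilon_{si} \sim \mathcal{N}(0, \sigma_n^2)$, i.i.d.

Stacking all observations of the group gives a joint Gaussian vector whose
covariance couples *every* pair of observations through $k_p$ and only
within-subject pairs through $k_m$. The five hyperparameters
$(\sigma_p^2, \ell_p, \sigma_m^2, \ell_m, \sigma_n^2)$ are estimated by
maximizing the log marginal likelihood (Cholesky factorization, analytic
gradients, L-BFGS-B in log-parameter space).

**The rhythmicity test.** The null model omits the shared component
($\sigma_p^2 = 0$, $\ell_p$ not free). The statistic
$\Lambda = 2(\hat\ell_{\mathrm{rhythmic}} - \hat\ell_{\mathrm{null}})$,
clipped at 0, is referred to the upper tail of $\chi^2_2$ (two extra free
hyperparameters, the standard Wilks count), and an analyte is called
rhythmic at the conventional 5% level. Because the null pins $\sigma_p^2$
to the boundary of the parameter space, the true null distribution of
$\Lambda$ is a mixture with more mass at zero than $\chi^2_2$, so this
test is *conservative* — the package's own size simulation (500 null
datasets at the study design; see `scripts/acceptance.R`) measures an
empirical size of roughly 1–2% at nominal 5%. A permutation-calibrated
p-value (times shuffled within each subject, refit, 999 permutations by
default) is available via `testRhythmicity(..., permute = TRUE)` for users
who want an exact-size test at a much higher computational price.

**Acrophase.** For a rhythmic analyte, the posterior mean of $g$ given the
stacked data is computed on a 0.1 h grid over $[0, 24)$ (with its
pointwise posterior SD, which never exceeds $\sigma_p$), and the acrophase
is the earliest argmax of that mean. Peak times are reported in clock
hours; all recovery tests measure *circular* error.

**Gain classification.** Each analyte is tested separately in the control
and disease groups, and the pair of p-values is classified by a truth
table at level $\alpha$: rhythmic in both, gained in disease, lost in
disease, or not rhythmic. This mirrors an analysis that classifies by two
within-group tests rather than one interaction test; no between-group
amplitude test is attempted (out of scope).

## Why per-group, why period 24, why df = 2

Three genuinely open design choices, resolved as follows:

* **Per-group fitting.** The hierarchy is fitted independently per analyte
  per group. A joint fit with group offsets would borrow strength but
  entangle the two null hypotheses; two separate fits keep the gain/loss
  classification a clean function of two within-group tests.
* **Fixed period.** Five samples per subject cannot identify an unknown
  period, and the biological hypothesis is specifically a 24 h rhythm; the
  period is therefore a constant of the model, not a parameter.
* **df = 2.** The rhythmic model frees two extra hyperparameters
  ($\sigma_p^2$, $\ell_p$); Wilks counting gives $\chi^2_2$. The boundary
  issue noted above makes this conservative rather than anticonservative,
  which is the safe direction for a discovery screen.

## Preprocessing

* **Imputation (before normalization).** Missing cells — sporadic in this
  design, e.g. a single broken vial — are filled deterministically by
  linear interpolation in time within each (subject, analyte) stratum,
  carrying the nearest observed value at the boundaries. This replaces
  stochastic multiple imputation deliberately: single deterministic
  imputation makes every downstream number reproducible, and at the
  missingness levels this design anticipates (~1%) the difference is
  immaterial. Subjects retaining fewer than two observed visits are
  dropped with a warning.
* **Normalization.** Each (subject, analyte) stratum is standardized to
  mean 0, sample SD 1 (n−1 denominator). This removes inter-individual
  level and scale differences so that the GP operates on comparable
  within-subject fluctuations. Constant strata (SD = 0) cannot be
  standardized; they are excluded from rhythm analysis and logged, never
  jittered.
* **Time handling.** Clock times run in absolute hours; samples taken
  after midnight are unwrapped into $[24, 48)$. Periodicity is handled by
  the kernel, never by folding the data onto $[0, 24)$.

## The synthetic-data generator

`simulateLipidome()` draws from the generative counterpart of the model,
at the clinical design's defaults: 2 groups × 10 subjects × 5 samples at
6-h intervals from 18:00, a 116-analyte panel (ceramide-majority, with
eicosanoid and endocannabinoid names, all parseable by the nomenclature
module), subject-deviation SD 0.5 with a 6 h Matérn lengthscale, unit
noise SD, and 1% missingness. Rhythmic fractions default to 0.10
(control) and 0.30 (disease) — a disease-driven gain of rhythm of the
kind the model is built to detect; the exact fractions in real serum
panels are unknown and these are fixed package defaults, not fitted
quantities.

Two signal modes exist because they serve different tests:

* `"cosinor"` (default): the shared curve is exactly
  $a\sqrt{2}\cos(2\pi(t - \phi)/24)$ with known acrophase $\phi$ and SD
  $a$ — the only mode in which phase-recovery error is well defined.
* `"gp"`: the shared curve is an actual draw from the periodic-kernel GP
  — faithful to the analysis model (used for kernel-covariance
  model-faithfulness checks) but with random phase.

Ground truth (rhythmic flag, acrophase, amplitude) is attached as
metadata only — never as data columns — so pipeline code cannot peek. One
master seed drives everything; per-analyte substreams are derived
deterministically from (seed, analyte index), making every dataset
bit-reproducible.

What the generator does *not* emulate: LC-MS/MS measurement artifacts
(batch effects, limits of detection, heteroscedastic intensity noise),
non-Gaussian tails, and correlation *between* analytes. Passing tests on
this generator therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not robustness to every
failure mode of real lipidomics data.

## Numerical choices

* Optimization in log-parameter space; bounds $[10^{-9}, 10^3]$ on
  variances and $[0.05, 50]$ on lengthscales; 5 restarts from a fixed
  lattice plus, for the rhythmic model, a warm start at the null optimum
  with $\sigma_p^2 = 10^{-9}$. The warm start guarantees
  $\hat\ell_{\mathrm{rhythmic}} \ge \hat\ell_{\mathrm{null}} - 10^{-6}$,
  so the LR statistic is never materially negative. The variance floor is
  $10^{-9}$ rather than a larger value precisely so that the rhythmic
  family contains the null to well inside that tolerance.
* Cholesky factorizations add a jitter of $10^{-8} \times$ mean diagonal
  (escalated tenfold on failure); at the unit-variance data scale this
  never moves a likelihood at the precision any test uses.
* On 6-hourly data the Matérn and noise variances are only jointly
  identified (a ~2 h lengthscale Matérn is invisible between samples);
  tests and interpretation should treat $\sigma_m^2 + \sigma_n^2$ as the
  meaningful "non-rhythmic variance", not either addend alone.
* Acrophase ties (flat stretches of the posterior mean) break to the
  earliest hour; a flat curve raises an error rather than returning an
  arbitrary phase.
* JTK templates are rounded at $10^{-12}$ before tie detection: cosine at
  quarter-period points evaluates to $\pm 10^{-16}$ rather than 0, and
  unrounded values would silently break the tie structure Kendall's tau
  depends on.

## The JTK-style detector

For the balanced, evenly sampled animal-model arm, `jtkTest()` provides an
independent nonparametric check: Kendall's tau of the data against cosine
templates over a phase grid (default: the sampling interval), one-sided
exact p-values when tie-free, a seeded permutation tail otherwise, and
Bonferroni correction over the template family; `adjustBH()` /
`jtkScreen()` apply Benjamini–Hochberg across analytes. This is a
deliberate simplification of the original JTK-CYCLE (no Harding
tau-distribution tables, no asymmetry search): the package needs an
independent detector with known conservative size, not a bit-exact clone.
On strong signals (amplitude/noise ≥ 4) it agrees with the GP test on ≥
95% of calls — that agreement is itself one of the package's tests.

## Problem sizes used by the test suite

The suite and the acceptance script run simulation studies at the study
design scale: 500 null datasets for test size, 50 replicates per
amplitude for power monotonicity and acrophase recovery, a 40-analyte
mixed panel for the end-to-end gain classification, and 300–400 null
series for the JTK size check. These sizes give Monte-Carlo standard
errors comfortably below every margin tested while keeping a full run in
a few minutes.

## A worked example

```{r example, eval = FALSE}
cfg <- SimulationConfig(nAnalytes = 40, fractionRhythmic = c(0.3, 0.5),
                        amplitude = 2, seed = 11)
res <- runPipeline(simConfig = cfg, seed = 11)
res$summary$gain_partition
table(res$calls$category)
```

## Known limitations

* The chi-squared reference is conservative under the boundary null; raw
  5% calls understate the true discovery rate slightly. The permutation
  option calibrates this at ~2000× the cost.
* Per-analyte testing at raw $\alpha$ does not control the family-wise or
  false-discovery rate across a 116-analyte panel; `multiplicity = "BH"`
  is available and recommended when the scientific claim is about the
  *set* of rhythmic species.
* Acrophase precision is limited by design sparsity: with 5 samples per
  subject, circular errors of ~1 h are typical at amplitude 1 (the
  package's own recovery test quantifies this).
* The generator's independence across analytes means panel-level
  summaries (counts per class) have smaller variance in simulation than
  they would under realistic inter-lipid correlation.
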