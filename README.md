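# LipidRhythm

Detection of gained (and lost) 24-hour circadian rhythmicity in sparse,
multi-subject serum lipidomics time series — the setting of clinical
chronobiology studies where each participant contributes only a handful of
samples across one day, and the scientific question is whether a lipid
species oscillates *as a group-level rhythm*, e.g. ceramides becoming
rhythmic in rheumatoid arthritis but not in healthy controls. The package
is aimed at analysts of targeted lipidomics / metabolomics time courses
(human or animal) who need a rhythm test that respects between-subject
heterogeneity at n ≈ 5 samples per subject.

## The model

For one analyte in one group, with normalized concentration `y_si` of
subject `s` at hour `t`:

    y_si(t) = g(t) + f_s(t) + e_si

* `g` — shared rhythmic component, a Gaussian process with the periodic
  (exp-sine-squared) kernel
  `k_p(t,t') = σ²_p exp(−2 sin²(π(t−t')/24) / ℓ²_p)`, period fixed at
  24 h;
* `f_s` — subject-specific deviation, an independent Matérn 3/2 GP,
  `k_m(r) = σ²_m (1 + √3 r/ℓ_m) exp(−√3 r/ℓ_m)`;
* `e_si` — i.i.d. Gaussian noise, variance `σ²_n`.

Hyperparameters are estimated by maximum marginal likelihood (Cholesky,
analytic gradients, multi-restart L-BFGS-B). Rhythmicity is tested by the
likelihood ratio against the null model without `g`:
`Λ = 2(ℓ_rhythmic − ℓ_null)` referred to the upper tail of χ²₂ at the 5%
level (conservative, since σ²_p sits on the boundary under the null).
Acrophase = earliest argmax of the posterior mean of `g` on a 0.1 h grid.
Analytes are classified across groups by the two within-group tests:
rhythmic in both / gained in disease / lost in disease / not rhythmic.

A simplified JTK-style detector (cosine templates × Kendall's tau,
Bonferroni over phases, BH across analytes) serves balanced, evenly
sampled designs such as mouse serum collections, and doubles as an
independent cross-check on the GP calls. A synthetic-data generator
reproduces the two-group clinical design (10 subjects/group, 5 samples at
6-h intervals from 18:00, 116-analyte ceramide-majority panel) for
calibration and power studies; ceramide labels (`CER[N(18)DS(24)]` etc.)
are parsed into sphingoid-base / fatty-acid classes for per-class
summaries.

## Worked example

```r
library(LipidRhythm)

cfg <- SimulationConfig(nAnalytes = 40, fractionRhythmic = c(0.3, 0.5),
                        amplitude = 2, seed = 11)
res <- runPipeline(simConfig = cfg, seed = 11)

table(res$calls$category)
#> rhythmic_in_both     gained_in_RA       lost_in_RA     not_rhythmic
#>                7               13                5               15

res$results[res$results$analyte == "CER[N(16)DS(18)]", c(1:3, 5, 6, 8)]
#>             analyte   group      lr_stat      p_value rhythmic acrophase
#> 2  CER[N(16)DS(18)] healthy 5.108380e-05 9.999745e-01    FALSE        NA
#> 42 CER[N(16)DS(18)]      RA 8.629812e+01 1.822222e-19     TRUE        20
```

Here 40 simulated lipids (30% rhythmic in the control group, 50% in the
disease group, shared-component SD 2) are imputed, normalized per subject
and per lipid, fitted, and classified. `CER[N(16)DS(18)]` is flat in
controls (Λ ≈ 0, p ≈ 1) but strongly rhythmic in the disease group
(Λ = 86.3, p = 1.8e−19) with estimated peak concentration at 20:00 — a
"gained" ceramide. `res$summary` carries the per-class rhythmic counts and
the gained/lost/both/none partition; with `outDir =` set, the pipeline
writes `results.csv`, `calls.csv`, `posteriors.csv`, `summary.json`, the
resolved `config.yaml` and a run log.

A thin command-line wrapper with `simulate` / `run` / `jtk` subcommands is
installed at `inst/scripts/lipidrhythm.R`.

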