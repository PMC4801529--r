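# bitterpls

Robust partial least squares calibration of electronic-tongue (e-tongue)
sensor data against human taste-panel bitterness scores.

## The problem

The bitterness of herbal decoctions is traditionally graded by a trained
human panel on a five-rank intensity scale (ranks I–V over 0.5–5.5,
anchored by berberine hydrochloride reference solutions).  An e-tongue —
an array of seven cross-sensitive potentiometric sensors (ZZ, CA, DA,
BA, GA, BB, AB) — can replace the panel once a calibration model maps
its sensor fingerprint to panel intensity.  The catch: such calibration
sets are small (a few dozen samples) and reliably contaminated by
outliers — subjective panel scores, carry-over residue from strongly
bitter samples, extreme-pH matrices — and classical regression breaks
down exactly there.

`bitterpls` implements the calibration the robust way:

* **Panel processing** — iterative two-sided Grubbs screening of
  assessor scores, mean ± sd summaries, rank-scale mapping.
* **Sensor ingest** — replicate-series averaging (mean of the last four
  acquisition cycles) and assembly of the n × 7 sensor matrix.
* **Robust PLS (RSIMPLS-style)** — SIMPLS weight extraction from a
  robust center/scatter of the joint [X y] block (projection-pursuit
  outlyingness + FAST-MCD), followed by a reweighted score regression.
  Coefficients are reported in raw sensor units:
  `I = c_ZZ·ZZ + … + c_AB·AB + c₀`.
* **Latent-variable selection** — leave-one-out cross-validation and the
  robust component selection statistic
  `RCS_k = sqrt(γ·R-RMSECV_k² + (1−γ)·R-RMSE_k²)`, with an explicit
  plateau rule for the chosen k.
* **Outlier maps** — standardized residual (Sr, cutoff 2.5) versus score
  distance (SD, cutoff `sqrt(χ²_{k,0.975})`), classifying samples as
  regular, good leverage, bad leverage or vertical; bad-leverage and
  vertical outliers are excluded, good leverage retained, manual
  overrides honored.
* **Benchmarks** — MLR, classical SIMPLS and RBF-kernel LSSVM (LOOCV
  grid tuning), evaluated before and after outlier screening.
* **A synthetic study generator** — e-tongue-like data with known ground
  truth and planted outliers of all three types, so every stage is
  testable end to end.

## Worked example

```r
library(bitterpls)

# a 35-sample synthetic study with 6 planted outliers
# (1 good leverage, 3 bad leverage, 2 vertical)
sim    <- generate_dataset(synthetic_config(seed = 3,
            contamination = study_contamination()))
report <- run_pipeline(pipeline_config(dataset = sim$dataset,
            run_benchmarks = FALSE, seed = 3))
print(report)
```

```
== e-tongue bitterness evaluation report ==
samples: 35 (29 retained after screening)
latent variables: k = 4
pre-screen robust fit: R2 = 0.9647, weighted robust RMSE = 0.2015
pre-screen calibration equation:
  I = (0.0009981) * ZZ + (-0.00079506) * CA + (0.00099372) * DA + (0.00043599) * BA + (0.0018687) * GA + (-0.00040156) * BB + (0.00066577) * AB + -6.1207
excluded: 2, 9, 10, 11, 23, 24
post-screen calibration equation (alpha = 1 retrain):
  I = (0.00093014) * ZZ + (-0.00065093) * CA + (0.00093789) * DA + (0.00041651) * BA + (0.0018334) * GA + (-0.00033296) * BB + (0.00048077) * AB + -5.7062
```

Reading the output: the RCS curve plateaued at **k = 4** latent
variables; the robust fit explains the retained samples with R² 0.96
and a robust residual scale of about 0.2 intensity units; six samples
were flagged and excluded — the five planted bad-leverage/vertical
outliers plus one borderline sample — while the planted good-leverage
sample (id 35) was flagged but deliberately retained:

```r
print(report$diagnostics)
#> outlier map: |Sr| cutoff 2.50, SD cutoff 3.3382
#>       regular good_leverage  bad_leverage      vertical
#>            28             1             3             3
#> flagged: 2, 9, 10, 11, 23, 24, 35
```

The calibration equation's coefficients sit at the 10⁻⁴–10⁻³
magnitudes typical of raw potentiometric units (sensor baselines are of
order 10³), with an intercept of a few intensity units.  After
exclusion, the model is retrained with the outlier fraction set to zero
(`alpha = 1`, the classical path) on the 29 retained samples.

A command-line front end wraps the same functions
(`inst/cli/bitterpls`): subcommands `simulate`, `screen`, `fit`, `run`
and `benchmark`.

## Package layout

```
R/              panel, ingest, mcd, robpca, rsimpls, selection,
                diagnostics, benchmarks, synthetic, pipeline
tests/testthat/ unit, property and acceptance suites
vignettes/      methods vignette (model, assumptions, design choices)
inst/extdata/   published 35-sample panel reference table
inst/cli/       command-line front end
scripts/        acceptance script
```
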