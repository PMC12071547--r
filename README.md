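# manopull

Analysis of eight-channel **pull-through anorectal manometry** for the
differential diagnosis of an anteriorly located anal opening in infants:
is the opening *surrounded by* the sphincter complex (anterior anus, an
anatomical variant) or does it lie *outside* it (a mild anorectal
malformation that may need surgery)? The package is aimed at pediatric
surgery / motility groups who record radial pull-through pressure
profiles and want a reproducible, scriptable alternative to manual
vendor-software readings.

## What it computes

For each pull-through maneuver (catheter withdrawn through the anal canal
at ~1 cm/s, 8 radial channels), the package

1. locates the **high-pressure zone** (HPZ) — the axial level maximizing
   the smoothed 8-channel mean, taken as the sphincter complex;
2. reads the raw circumferential pressures there and forms
   - the mean circumferential pressure
     P̄_circ = (1/8) Σ p_i,
   - the mean anterior pressure
     P̄_ant = (p₁ + p₂ + p₈)/3 (channels 1, 2, 8 face the anterior midline),
   - their ratio R = P̄_ant / P̄_circ;
3. aggregates min/mean/max of the three metrics over at most the first
   six maneuvers per patient.

A combined cut-off rule flags an anus outside the sphincter complex when
**mean anterior pressure < 75 mmHg AND mean ratio < 0.7** (strict,
configurable). Diagnostic accuracy comes with exact Clopper–Pearson 95%
intervals; group contrasts use a tie-corrected Mann–Whitney U
(statistic reported as min(U₁, U₂), no continuity correction, exact
enumeration available for small samples) and the uncorrected Pearson
chi-square for 2×2 tables — all implemented in-package and cross-checked
against independent oracles in the test suite.

Because clinical recordings of this kind are not publicly shareable, a
**synthetic cohort generator** produces pull-through recordings with the
assumed structure (Gaussian high-pressure zone, raised-cosine anterior
deficit, per-channel noise, agitation artifacts, two phenotype groups,
group-dependent constipation prevalence). See
`vignettes/manopull-methods.Rmd` for the model and its calibration.

## Worked example

```r
library(manopull)

cfg     <- simulation_config(seed = 42)     # 12 abnormal vs 26 normal patients
cohort  <- simulate_cohort(cfg)
metrics <- cohort_metrics(cohort)           # per-maneuver + per-patient tables
report  <- cohort_report(metrics, sweep = FALSE)
print(report)
```

```
Cohort report (38 patients)

Group comparison (means by group, Mann-Whitney U):
          metric aggregate group_a_mean group_b_mean  u        p n_a n_b
 circumferential       min       107.69       145.04 38 2.11e-04  12  26
 circumferential      mean       113.15       148.32 43 3.87e-04  12  26
 circumferential       max       123.12       153.06 71 7.60e-03  12  26
        anterior       min        62.19       137.09 17 1.27e-05  12  26
        anterior      mean        68.30       142.40 18 1.47e-05  12  26
        anterior       max        79.35       149.06 23 2.96e-05  12  26
           ratio       min         0.56         0.92  3 1.55e-06  12  26
           ratio      mean         0.60         0.95  5 2.12e-06  12  26
           ratio       max         0.65         0.98  6 2.47e-06  12  26

Diagnostic accuracy (TP 10, FN 2, TN 25, FP 1)
  sensitivity: 83% (95% CI 52-98%)
  specificity: 96% (95% CI 80-100%)

Constipation: 50% (A) vs 8% (B), X2 = 8.84, p = 0.0029
```

Reading this: simulated group A (abnormal sphincter) shows markedly lower
anterior pressures (68 vs 142 mmHg) and ratios (0.60 vs 0.95) at the
high-pressure zone, the 75 mmHg / 0.7 rule recovers 10 of the 12 abnormal
patients while misclassifying 1 of 26 normal ones, and constipation is
concentrated in the abnormal group — the pattern the measurement chain is
designed to expose. `plot_group_boxplots(metrics$patients)` and
`plot_cutoff_scatter(metrics$patients)` draw the corresponding figures;
`threshold_sweep()` maps accuracy over a whole threshold grid.

Cohorts round-trip through a documented interchange format (long CSV +
JSON sidecar) via `write_cohort()` / `read_cohort()`, and
`inst/scripts/manopull` exposes the pipeline as a command line
(`simulate` / `analyze` / `report` / `run-all`) driven by a YAML or JSON
config (`read_pipeline_config()`).

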