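---
title: "Methods: pull-through manometry of the anal sphincter complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pull-through manometry of the anal sphincter complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manopull)
```

## The clinical problem

In infants with an anteriorly located anal opening, the decisive question
is whether the opening is *surrounded by* the sphincter complex (an
anatomical variant, the "anterior anus", requiring no surgery) or lies
*outside* it (a mild anorectal malformation such as a perineal fistula,
which may need anoplasty). The reference standard — electrical muscle
stimulation under general anesthesia — is invasive; anorectal manometry
(AM) offers an outpatient alternative that probes the same anatomy through
pressure.

`manopull` implements the manometric measurement chain for this question:
an eight-channel water-perfused catheter is placed in the rectum and
withdrawn through the anal canal at about 1 cm/s, so each time sample maps
to an axial position. Radial channels record circumferential pressures; if
the sphincter is absent anteriorly, the channels facing the anterior
midline read systematically lower at the level of the sphincter complex.

## The measurement procedure

For one pull-through maneuver:

1. **High-pressure zone (HPZ).** The axial level taken as the sphincter
   complex is the sample maximizing the 8-channel mean pressure after a
   short moving-average smoothing (default window 3 samples, edge
   truncated). Ties break toward the rectal side. Smoothing serves peak
   *localization* only; the metric values below are the raw pressures at
   the chosen level, preserving what a clinician would read off.
2. **Metrics at the HPZ.** With the eight raw channel pressures
   $p_1,\dots,p_8$ at that level,
   $$\bar P_{\text{circ}} = \tfrac18\sum_{i=1}^8 p_i, \qquad
     \bar P_{\text{ant}} = \tfrac13 (p_1 + p_2 + p_8), \qquad
     R = \bar P_{\text{ant}} / \bar P_{\text{circ}}.$$
   Channels 1, 2 and 8 face the anterior midline (see geometry below).
   $R$ is undefined when $\bar P_{\text{circ}} \le 0$; such maneuvers are
   flagged and excluded, never zero-filled.
3. **Per-patient aggregation.** At most the first six maneuvers (in
   acquisition order) are analyzed per patient; for each of the three
   metrics the minimum, mean and maximum across the used maneuvers are
   kept. The cap of six reflects the clinical analysis protocol; excess
   maneuvers are recorded but ignored, and dropped (undefined-ratio)
   maneuvers are tallied.

Each maneuver is analyzed independently — with several pull-throughs per
exam the HPZ is re-localized per maneuver, since manual pulls do not share
an axial registration.

### Channel geometry

The angular layout of an eight-channel radial catheter is conventional,
and we fix it as: channel 2 on the anterior midline (0°), channels 1 and 8
at −45° and +45°, and channels 3–7 filling the circle at 90°, 135°, 180°,
225°, 270°. The set covers the circle at 45° spacing and makes
channels 1, 2, 8 a contiguous, symmetric 135° anterior sector — the
natural reading of "three anterior channels". Note the numbering is a
labelling convention, not a claim about physical wiring order; only the
angle *set* and the anterior sector matter to the analysis.

The axial coordinate is 0 at the anal verge, positive toward the rectum,
and decreases during a pull. Neither choice is forced by the physics; both
are embedded in the interchange format so readers and writers agree.

## The decision rule and its evaluation

A patient is flagged as having an anus outside the sphincter complex when
(strictly)

$$\bar P_{\text{ant}}^{\text{(mean)}} < 75 \text{ mmHg}
  \quad\text{AND}\quad R^{\text{(mean)}} < 0.7 .$$

The conjunction with strict inequalities matches the rectangular cluster
such cases form in the anterior-pressure-versus-ratio plane; the
combination, the aggregate fed to the rule, and both thresholds are
configurable (`cutoff_rule()`), and `threshold_sweep()` evaluates a whole
grid with the Youden index as a summary.

Sensitivity and specificity against ground truth (group A = abnormal
sphincter = condition positive) carry **exact Clopper–Pearson intervals**,
computed by inverting the binomial tail tests (beta-quantile form). Exact
intervals are conservative by construction — their coverage is at least
nominal — which is the right property for small diagnostic series
(n ≈ 10–30 per class). For the worked case of 8 successes in 10 trials the
95% interval is (0.444, 0.975).

## Group statistics

Both tests are implemented from first principles in this package; the
standard library routines serve as independent cross-checks in the test
suite, never as the implementation.

**Mann–Whitney U.** Pooled midranks; $U_1 = R_1 - n_1(n_1+1)/2$; the
reported statistic is $\min(U_1, U_2)$ (the convention of the common
online calculators; both values are retained). The two-sided p-value uses
the tie-corrected normal approximation *without* continuity correction,
$$\sigma_U^2 = \frac{n_1 n_2}{12}\Bigl[(N+1) -
  \frac{\sum_t (t^3 - t)}{N(N-1)}\Bigr],$$
with the convention $p = 1$ when every observation is tied ($\sigma_U = 0$).
A complete-enumeration exact p-value is available for small samples
(`exact = TRUE`). The uncorrected approximation deviates from the exact
p-value by at most about one step of the discrete null distribution
($\approx 0.5/\sigma_U$; e.g. ~0.05 at $n_1 = n_2 = 8$), which is why the
exact option exists for very small series.

**Chi-square.** The uncorrected Pearson statistic for 2×2 tables,
$X^2 = N(ad-bc)^2/[(a\!+\!b)(c\!+\!d)(a\!+\!c)(b\!+\!d)]$, df = 1, with
the Yates correction as an option. A zero marginal yields an "undefined"
finding rather than an error, and small-count tables carry a warning
finding.

**Report.** `build_group_report()` produces the nine-row table (3 metrics
× min/mean/max) with group means, U and p per row. No multiplicity
adjustment is applied across the nine rows by default — they are reported
as raw descriptive comparisons. The unit of analysis defaults to the
patient (per-patient aggregates); a per-maneuver mode exists for
sensitivity analyses, because with ≤6 maneuvers per patient the two give
very different effective sample sizes.

## The synthetic cohort generator

Real pull-through recordings for this clinical question are not publicly
available, so the package ships a generator that produces cohorts with the
statistical structure the analysis assumes. It is first-class, tested
code — the validation studies in the test suite all run on it.

### Generative model

A patient's sphincter is summarized by a `sphincter_phenotype`: the
noise-free pressure field is

$$P(z,\theta) = b + A\,
  e^{-(z-z_0)^2/2\sigma^2}\,\bigl[1 - d\, w(\theta-\theta_0)\bigr],$$

with baseline $b$ (mmHg), amplitude $A$ (mmHg), axial center $z_0$ and
spread $\sigma$ (cm), anterior deficit $d \in [0,1]$ and a raised-cosine
angular window $w(\phi) = \tfrac12(1+\cos(\pi\phi/h))$ of half-width
$h = 90°$ about the anterior midline. $d = 0$ is a fully circular
sphincter (all channels identical, ratio exactly 1); $d = 1$ drives the
mid-anterior channel to baseline at the peak — the manometric signature of
a complete anterior sphincter absence. The smooth window avoids
non-physiological pressure cliffs between adjacent channels; with $h=90°$
the deficit touches the anterior sector strongly ($w = 1, \tfrac12,
\tfrac12$ at channels 2, 1, 8) and the lateral channels only marginally,
so the downstream ratio is strictly decreasing in $d$ — a property the
test suite checks on a grid.

A maneuver samples this field along the pull (default 1 cm/s at
10 samples/s, i.e. 1 mm axial resolution — fine enough that peak
discretization error is negligible against measurement noise) over a 6 cm
span starting 3 cm rectal of the verge, which comfortably contains an
infant sphincter complex. Independent Gaussian noise (default sd 8 mmHg)
is added per sample and channel, and with probability 0.1 a maneuver
receives one transient positive bump on all channels simultaneously
(default 40 mmHg peak, ~0.15 s support) — an agitation artifact, since
infants are not sedated for AM and are not always at rest. Pull-speed and
amplitude jitter knobs exist for sensitivity analyses but default to 0.

### Cohort structure and priors

Default cohorts mirror the clinical series the method targets: 12
abnormal-sphincter patients (group A) and 26 normal ones (group B); 1–10
maneuvers per exam drawn as $1 + \mathrm{Bin}(9, 7/18)$ (mean 4.5);
constipation flags Bernoulli with 45% (A) and 15% (B). One phenotype is
drawn per patient and shared by all of that patient's maneuvers, so
between-patient variation dominates and between-maneuver variation comes
from measurement noise — the simplest decomposition consistent with a
fixed anatomy being measured repeatedly.

Priors per group (truncated normals; Beta for the deficit):

| parameter | group A | group B |
|---|---|---|
| baseline $b$ | N(15, 3) mmHg | N(15, 3) mmHg |
| amplitude $A$ | N(120, 25) mmHg | N(135, 28) mmHg |
| axial center $z_0$ | N(1.0, 0.25) cm | same |
| axial spread $\sigma$ | N(0.6, 0.1) cm | same |
| deficit $d$ | Beta(mean 0.92, conc. 10) | Beta(mean 0.08, conc. 13), 12% mixed with U(0.35, 0.85) |
| angular offset $\theta_0$ | N(0°, 10°) | same |

The deficit priors encode the clinical contrast: abnormal cases typically
show complete anterior sphincter absence (d near 1), normal ones an anus
essentially encircled by muscle, with a minority showing a moderately
weaker anterior segment (the uniform mixture component). Amplitudes and
the deficit means were **calibrated by simulation**: with these values a
large cohort's group mean anterior pressures land near 61 and 136 mmHg and
mean circumferential pressures near 108 and 144 mmHg — the regime the
cut-off rule was designed for — while the group histograms still overlap
slightly, so the rule's sensitivity and specificity are high but not
perfect. The calibration was done once, before the validation suite was
frozen, and is not a tuning knob.

### What the generator does *not* emulate

Real recordings have serially correlated perfusion noise, catheter-wall
adhesion effects, squeeze responses evoked by the pull itself, operator
speed drift within a maneuver, and missing or mislabelled channels. None
of these are modelled (speed jitter exists but is off by default). Tests
passing on synthetic cohorts therefore validate the *computational chain*
— geometry, localization, aggregation, statistics — not the clinical
performance of the cut-offs on real patients, which only a prospective
series can establish.

## Numerical and degenerate-input choices

- HPZ smoothing truncates the window at the recording edges (no padding);
  ties in the smoothed profile resolve to the earliest (most rectal)
  sample, making the constant recording return the first index.
- Aggregation over zero valid maneuvers produces a per-patient failure
  record (`ok = FALSE`), excluded from group statistics and flagged.
- `mann_whitney_u` returns $p = 1$ (not NaN) when the tie-corrected
  variance is zero; `chi_square_2x2` reports a zero marginal as a finding.
- Exact interval closures: lower bound 0 at $k = 0$, upper bound 1 at
  $k = n$.
- Truncated-normal prior draws clip at small positive floors (amplitude
  ≥ 10 mmHg, $\sigma$ ≥ 0.2 cm) rather than resampling; with the default
  priors the clipping region carries negligible mass.
- The interchange CSV stores channels 1-based and pressures unrounded;
  round-tripping a cohort is lossless to numeric printing precision.

## Problem sizes

The validation studies run at sizes chosen to make Monte-Carlo error
small relative to the margins being checked: prior-ordering checks at 500
draws per group, constipation-frequency recovery at 400–1000 patients per
group, parameter-recovery and rule-accuracy studies at 500 patients per
group, and interval-coverage checks at 10,000 binomial draws. The
coverage and recovery margins (e.g. anterior means within 10% of their
calibration targets, rates within 3 points) are design statements about
the generator, checked — not fitted — by the suite.

## Known limitations

- The angular layout of the anterior channels is a convention; a catheter
  wired differently would need its angle map supplied to
  `pull_through_recording()`.
- The per-maneuver HPZ choice (rather than one level per exam) can pick
  different levels across maneuvers of one patient when the profile is
  flat or bimodal; the min/max aggregates absorb some of this.
- Reported U statistics at patient level are bounded by
  $n_1 n_2 = 312$ for a 12-vs-26 cohort; published series sometimes
  report larger U values, implying a maneuver-level unit of analysis —
  the package offers both, but they are not comparable.
- The chi-square test is asymptotic; for the small tables typical here
  the small-count finding should prompt an exact test elsewhere if the
  p-value is load-bearing.
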