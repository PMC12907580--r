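---
title: "Models and methods behind heattol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heattol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattol)
```

# The problem

The standardized heat tolerance test (HTT) is a 120-minute treadmill walk
(5 km·h⁻¹, 2 % grade, 40 °C / 40 % relative humidity) with continuous rectal
temperature (T_rec) and heart rate (HR) monitoring, used to judge whether an
individual thermoregulates adequately before returning to duty or sport
after exertional heat illness. A session is summarised into derived metrics
and then scored against a battery of published intolerance criteria. Raw HTT
records are typically not shareable, so the package pairs the analysis
pipeline with a synthetic cohort generator calibrated to published
sex-by-acclimation-state group statistics: every stage of the pipeline is
exercisable and testable without access to participant data.

# Per-session metrics

Series are piecewise linear between 5-min samples. Values at 60 and 120 min
use the stored sample when it exists and linear interpolation otherwise.
Design choices the source conventions leave open:

- **Peaks** are maxima over recorded samples — no extrapolation beyond the
  data.
- **Means** are time-weighted trapezoidal means, not arithmetic means of
  samples, so irregular grids do not bias toward densely sampled stretches.
- **Areas above a threshold** integrate `max(value − threshold, 0)` with the
  trapezoid rule after inserting linearly interpolated threshold-crossing
  times; for a piecewise-linear series the result is exact. The plain
  trapezoid rule applied to clamped samples would over-count segments that
  cross the threshold.
- **Exercise metrics exclude the seated equilibration period**: the series
  starts at exercise start (T0); the pre-exercise baseline enters only as
  the reference level of the baseline-adjusted area and the temperature rate
  of rise.
- **Missing samples**: measured sessions with a gap above 10 min are
  rejected; gaps above the nominal 5-min cadence are linearly bridged with a
  warning.
- The heart-rate area (`hr_auc`) is the area above the heart rate at
  exercise start, the direct analogue of the baseline-adjusted temperature
  area.

The thermal–circulatory ratio is the plain quotient `T_rec / HR` (°C·bpm⁻¹);
rates of rise divide the change (from the pre-exercise baseline for
temperature, from T0 for heart rate) by the exercise duration.

# The classification battery

Seven criteria, evaluated per session:

| criterion | rule (heat intolerant when) |
|---|---|
| `trec_385` | peak T_rec ≥ 38.5 °C |
| `hr_150` | peak HR ≥ 150 bpm |
| `plateau_045` | ΔT_rec(T120–T60) ≥ 0.45 °C |
| `tcr_t120` | TCR at 120 min ≤ 0.279 °C·bpm⁻¹ |
| `tcr_t60` | TCR at 60 min ≤ 0.32 °C·bpm⁻¹ |
| `schermann` | any of: ΔT_rec(T120–T60) ≥ 0.25 °C, peak HR ≥ 120 bpm, peak T_rec ≥ 38.2 °C |
| `pht` | supplied externally (proprietary score; may be HT / BHT / HI) |

Open points resolved here:

- **Any-time versus at-end exceedance.** The temperature and heart-rate
  thresholds are evaluated against session peaks: any exceedance during the
  test removes tolerant status. This is the conservative reading and matches
  the safety intent of the test. A sustained-exceedance variant (requiring
  the threshold to be held for a minimum duration) was considered and left
  out: the published criteria give no duration, and peaks of a monotone-ish
  strain trajectory make the distinction minor.
- **Composite logic.** The composite criterion defines *tolerance* as
  staying below all three cut-offs; a single exceedance classifies the
  session intolerant. This is the only logic consistent with it being the
  criterion with the highest intolerance rates while its individual
  thresholds are the lowest of the battery ("most stringent" = strictest
  gate for granting tolerant status).
- **Borderline labels.** Only supplied criteria can produce `BHT`; rate
  computation groups it with the intolerant class by default
  (`bht_as_hi = TRUE`), the published aggregation rule.
- **Early terminations.** Sessions not covering [60, 120] min raise an
  error in the plateau and TCR_T120 metrics rather than silently entering
  those criteria's denominators.
- The proposed sex-adjusted cut-offs (38.7 °C, 170 bpm) ship as a separate,
  clearly flagged experimental registry (`sex_adjusted_criteria()`), off by
  default: their sensitivity and specificity are unvalidated.

# Cohort statistics

2×2 classification-frequency tables are tested with the Yates
continuity-corrected chi-square — the correction is not a stylistic choice:
the published pooled chi-square values are reproduced exactly by the
corrected statistic and not by the uncorrected one (46.65 vs the printed
45.48 for the pooled pre/post table). Criterion-specific comparisons use the
two-sided Fisher exact test with the probability-mass rule (sum of
hypergeometric probabilities of tables no more probable than the observed
one); two-sided Fisher conventions differ, and the tests pin this one
against a full enumeration oracle. Effect sizes are Hedges' g with the
small-sample correction `J = 1 − 3/(4·df − 1)`, signed so that positive
values indicate higher values in the second (male) group. Group-comparison
dispatch follows the published recipe: Shapiro–Wilk normality screening at
α = 0.05, then Levene's test to choose pooled versus Welch t, otherwise
rank-based tests; α = 0.05 for the screening steps is a fixed convention of
this package (the source states the tests but not the screening level).
Bonferroni adjustment takes the family size explicitly so that a subset of a
comparison family can be adjusted against the full family.

Counts behind published percentages are reconstructed with
`counts_from_percent()` (nearest-integer rounding against the known
denominators: 21 females, 19 males, 7 criteria); the reconstruction is
validated by recovering all four published chi-square statistics.

# The synthetic cohort generator

## Trajectory models

Temperature during exercise follows a mono-exponential rise to plateau,

> T(t) = T0 + ΔT_eq · (1 − exp(−t/τ)),

the minimal model that can reproduce a start value, a 60-min value and a
120-min value simultaneously. Given a printed (T0, T60, T120) triple, the
identity `1 + exp(−60/τ) = (T120 − T0)/(T60 − T0)` yields τ and then ΔT_eq.
For the pooled naïve cohort (36.98, 38.12, 38.41 °C) this gives
τ ≈ 43.8 min and ΔT_eq ≈ 1.53 °C. The degenerate case T60 = T120 is the
fully plateaued limit, represented by τ = 0. Ratios ≥ 2 admit no
exponential solution and are rejected.

Heart rate follows fast on-kinetics plus linear cardiovascular drift,

> HR(t) = HR0 + ΔHR_fast · (1 − exp(−t/τ_h)) + drift · t,

with τ_h fixed at 10 min (on-kinetics are essentially complete well before
60 min, so the printed values cannot identify τ_h; 10 min is a standard
order of magnitude for heart-rate on-kinetics). The fast amplitude and the
drift slope are solved exactly from the 60- and 120-min values.

## Calibration and variance attribution

Parameters are calibrated per sex × timepoint cell to the printed group
means of: pre-exercise baseline temperature, temperature at T0/T60/T120 and
heart rate at T0/T60/T120, plus the printed anthropometrics per sex, the
relative-intensity means, and the environment statistics per timepoint. The
exercise-start temperature is baseline plus a per-cell offset (0.02–0.08 °C
as printed).

Between-subject spread cannot be uniquely attributed from three endpoint
SDs, so the defaults use the simplest identifiable scheme: a normal subject
effect on the starting level (SD = printed baseline/T0 SD) plus a normal
effect on the rise magnitude whose SD is solved from the printed 120-min SD;
for heart rate, level, fast-amplitude and drift components are solved from
the three printed SDs, clamped at zero where the printed SDs are
non-monotone in time (female post-acclimation heart-rate SDs decrease from
60 to 120 min). The printed means are the calibration contract; the printed
SDs are matched approximately under this attribution.

The temperature time constant τ is a per-cell constant by default
(`trec_tau_sd = 0`). Two reasons: the printed endpoints cannot identify a
kinetic variance component separately from the magnitude component, and a
random τ enters the model nonlinearly, so any τ spread biases the implied
endpoint means away from their calibrated values. When a positive
`trec_tau_sd` is configured, τ is drawn log-normally (median at the cell
value) to keep it positive.

## Subject structure, noise, truncation

- Subject latent effects are standard normals shared across the two
  timepoints with correlation ρ (default 0.6 — a plausible middle value for
  trait-like physiological stability across a one-week protocol; the source
  gives no estimate, so it is a configuration knob). ρ = 1 shares effects
  exactly; ρ = 0 decouples them.
- Measurement noise is additive i.i.d. normal per sample: 0.05 °C for the
  thermistor chain and 2 bpm for the chest-strap chain — small relative to
  between-subject SDs, consistent with instrument-grade precision.
- Draws whose noise-free trajectories leave 35.5–41 °C or 40–220 bpm (or
  with non-positive rise, implausible intensity, or non-positive sweat rate)
  are resampled.
- Sweat and hydration: per-session sweat rate per unit body surface area is
  drawn per sex (0.58 ± 0.14 / 0.75 ± 0.17 L·h⁻¹·m⁻² F/M). These published
  values describe the acclimation sessions, not the HTT itself, for which no
  sweat statistics are printed — a synthetic stand-in choice. Post-exercise
  mass follows from exact mass balance with 0.5 L fluid intake (the protocol
  provides 2 × 250 mL) and a small truncated-normal urine output. Urine
  specific gravity is drawn near 1.012 ± 0.005 so most simulated screenings
  clear.
- Oxygen uptake at the two in-test sampling blocks derives from the
  subject's relative intensity, V̇O₂max and mass, with small sampling noise;
  RER is drawn near 0.85 ± 0.03 (moderate walking).

## What the generator does and does not emulate

It reproduces the printed first moments per cell, plausible second moments,
the within-subject pre/post coupling, and 5-min-cadence measurement noise.
It does not emulate: non-exponential trajectory shapes (sigmoid onsets,
late-session accelerations), correlated noise (sensor drift), menstrual
cycle phase effects, anthropometric–physiological cross-correlations (a
subject's fitness does not inform their trajectory beyond the sex cell), or
the acclimation intervention sessions themselves. Passing tests therefore
demonstrate calibration and internal consistency of the pipeline, not
validity of any classification criterion on real data.

A known discrepancy is carried deliberately: the printed endpoint means
imply a pooled naïve-cohort final-hour rise of 38.41 − 38.12 = 0.29 °C,
while the directly printed mean of that statistic is 0.30 ± 0.19 °C (the
printed per-sex means 0.24/0.35 °C likewise disagree with the per-sex
endpoint differences 0.21/0.37 °C, and the printed ΔT_rec mean 1.49 °C with
the endpoint difference 1.43 °C). The generator calibrates to the endpoint
means — they constrain the whole trajectory, not just one contrast — so
simulated cohorts average ≈ 0.29 °C for the final-hour rise.

# Problem sizes and numerical conventions

The test suite generates cohorts of up to 5000 participants per sex for
moment-recovery checks and 1000 per sex for the plateau-statistic check;
these sizes put Monte-Carlo standard errors an order of magnitude below the
quantities being checked while keeping the default suite in the
tens-of-seconds range. The simultaneous moment-recovery check across 28
cell-level means uses a Bonferroni-adjusted 3-SE bound: a per-comparison
2-SE bound would falsely fail a perfectly calibrated generator in most runs.
Area computations are exact for piecewise-linear series (crossing
insertion); comparisons against the dense-grid oracle are at 10⁻⁶ relative
tolerance. All randomness flows through a single integer seed;
`generate_cohort()` restores the caller's RNG state.

# Known limitations

- Printed group SDs of derived metrics are matched only approximately
  (variance attribution above), so dispersion-sensitive statistics on
  synthetic cohorts (e.g. criterion rates) approximate but do not reproduce
  the published rates.
- The PHT score is never computed — the algorithm is proprietary — and
  enters only as supplied labels.
- Repeated-measures ANOVA and linear mixed-effects trajectory models are
  out of scope; the summary table covers the paired, two-group and
  contingency statistics.
- The hydration screen, sweat and calorimetry calculations assume the
  standard 120-min protocol conventions (1 kg ≡ 1 L, small-angle treadmill
  work, non-protein RER partition with 21.13/19.62 kJ·L⁻¹ O₂ equivalents).
  Net heat production subtracts external work; both conventions (M and
  M − W) are reported so either can be used downstream.
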