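---
title: "Validation methods: agreement, equivalence and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation methods: agreement, equivalence and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearagree)
```

## What this package analyses

A wearable-validation study records, within each participant, the same
physiological quantities twice: once with the wrist device under test and
once with a clinical reference (ECG for heart rate, indirect calorimetry for
energy expenditure and respiration, a waist-mounted counter for steps),
while the participant follows a scripted laboratory protocol. The analysis
then asks two different questions:

1. **Equivalence** — is the device's session-level output *close enough* to
   the reference, in the sense that the ratio of the two lies inside a
   pre-declared margin? This is a TOST (two one-sided tests) question, not a
   difference test: failing to detect a difference is not evidence of
   agreement.
2. **Agreement description** — how large are the errors, second by second
   and epoch by epoch (ME, MAE, MPE, MAPE, coverage, Bland-Altman limits)?

`wearagree` implements both, plus the activity-recognition confusion matrix
and the protocol bookkeeping around them.

## The paired log-ratio TOST

Margins for physiological quantities are naturally multiplicative (±10%,
±15%), so the test operates on logs: with paired positive session values
$x_i$ (device) and $y_i$ (reference), $d_i = \log x_i - \log y_i$ is treated
as normal, and two one-sided paired $t$ tests are run against
$\log m_\mathrm{low}$ and $\log m_\mathrm{high}$ with $n-1$ degrees of
freedom. Equivalence requires both $p < \alpha$.

Conventions, all of which were genuinely open choices:

* **Margins are literal ratio bounds.** "±15%" means the interval
  $[0.85, 1.15]$, which is asymmetric on the log scale. The reciprocal
  convention $[1/1.15, 1.15]$ can be expressed by passing those margins
  explicitly; nothing in the code assumes symmetry.
* **Natural logarithms throughout.** The TOST decision is base-invariant
  (the base cancels in the $t$ statistic — there is a property test for
  this), and all estimates are reported back on the ratio scale as
  geometric-mean ratios.
* **Two intervals are reported.** The conventional two-sided 95% CI of the
  ratio is what validation papers print next to an $\alpha = .05$ TOST,
  even though the decision-dual interval is the 90% one. Both are in the
  result (`ci_*` and `ci_tost_*`) so neither has to be recomputed.
* **Degenerate inputs.** If every $d_i$ is identical (a real possibility
  for integer-reported resting heart rate) the $t$ statistic is undefined;
  the implementation then decides by direct margin comparison and flags the
  result (`degenerate = TRUE`) with a warning rather than failing.

### Sample size

`sample_size_equivalence()` finds the smallest $n$ whose TOST power reaches
the target under $d \sim N(\log r, \sigma^2)$. Power is computed exactly by
integrating the joint one-sided rejection region over the $\chi^2$
distribution of the sample SD (no normal approximation, no independence
assumption between the two one-sided tests); a Monte-Carlo evaluator with
the same interface serves as a cross-check and fallback. Planning inputs of
the emulated study — geometric-mean ratio 0.925 with $\sigma_{\log} = 0.173$
at a ±15% margin for energy expenditure, 1.032 with 0.055 at ±10% for
resting heart rate — are exercised in the test suite; the energy outcome
dominates recruitment. The solver's recruitment count inflates by the
anticipated dropout fraction (default 10%). The study software originally
used for such calculations is proprietary and its internal routine
unpublished, so exact agreement with any specific historical recruitment
number is not a goal; the solver is instead validated by simulated power at
$n$ and $n - 1$.

## Alignment and epoching

All traces are put on a common 1-Hz integer-second clock
(`resample_to_1hz()`): linear interpolation for continuous quantities
(heart rate, energy-expenditure rate, respiration), previous-value hold for
cumulative counters (interpolating a counter would invent fractional steps),
nearest-sample for labels, and no extrapolation beyond the sampled range.
On synthetic data, which is natively 1 Hz, resampling is an exact identity
(tested); the choice of scheme only matters for irregular recordings.

Heart-rate comparison uses means over 10-second non-overlapping epochs
anchored at the start of the device/reference overlap. Two conservative
rules apply: a trailing partial epoch is dropped (padding would bias the
mean), and an epoch is valid only if **both** sources contribute at least
one sample in the window (`min_samples` raises this threshold). Coverage —
the percentage of valid epochs within 10 bpm and within 10% of the
reference — counts the boundary as within.

Time intervals are half-open `[start, end)` everywhere: schedules,
segmentation, rest means, step totals. This single convention is what makes
the segmentation a partition (property-tested) and the per-activity step
totals add up exactly to the combined row.

## Resting heart rate

Resting heart rate is the **lowest 5-minute median**: every 300-second
window fully inside the rest recording is scanned at 1-second steps, and
the minimum of the per-window medians is returned together with the
earliest window attaining it. The median (not the mean) makes the estimate
robust to transient artifacts; taking the lowest window finds the quietest
stretch of the rest period. Numerical conventions: even-length medians are
the mean of the two central order statistics (R's default), ties across
windows break to the earliest start, and windows never span annotated
segment boundaries in the free-living variant. An optional integer-bpm
rounding mode mirrors devices that report whole beats. The implementation
is verified against exhaustive enumeration on random traces.

Free-living resting heart rate (`free_living_resting_hr()`) restricts the
same scan to annotated awake-inactive time per day and flags days with less
than one window of annotated rest instead of guessing.

## The synthetic cohort

Because validation recordings are personal data and rarely deposited, the
package ships a simulator whose point is to give every downstream statistic
a known ground truth.

**Demographics** (`generate_cohort()`): age 41.2 (SD 14.4) years, weight
77.2 (10.2) kg, height 1.80 (0.10) m, resting heart rate 64 (7.3) bpm,
basal metabolic rate 1654 (216.7) kcal/day — the cohort profile of the
emulated study — drawn from normals clamped to physiologic bounds, with BMI
always derived from sampled weight and height.

**Protocol** (`build_protocol_schedule()`): a 15-minute seated rest, then
eleven 3-minute activities (treadmill flat and 5% incline, ergometer bike,
cross trainer, household chores, desk work, lying, standing, and outdoor
walking, cycling, running), each followed by a 3-minute rest — 81 minutes
in total. The trailing rest is included by default (`rest_after_last`)
because the protocol rests after *each* activity; disabling it gives a
between-activities-only layout.

**Latent physiology** (`generate_session()`): heart rate relaxes toward
`resting_hr_true + hr_offset(activity)` with a first-order time constant
(`hr_tau_s`, default 30 s — any smooth transition would do; this one is
closed-form per segment and configurable). Energy-expenditure rate relaxes
toward `bmr/1440 × ee_met_factor` with the same constant, which makes it
affine in the heart-rate excess within each activity — the classical
near-linear HR–VO₂ relationship. Steps accrue at the activity cadence;
respiration scales mildly with metabolic load above a 14 breaths/min
resting default. The per-activity intensities (offsets 0–60 bpm, cadences
95–160 steps/min, MET factors 1–8) are defaults chosen once from standard
exercise-physiology ranges; the protocol gives only speeds and loads, so
they are intentionally configurable columns of `activity_profiles()`.

**Observation model** (`device_error_model()`): each numeric quantity is
observed as `latent × ratio_bias × exp(η + ε_t)` with

* `ratio_bias` — multiplicative calibration error (dimensionless, default 1);
* `η ~ N(0, between_sd_log²)` — one draw per session. This session-level
  component exists because per-sample noise averages out over a
   4860-second session (and would contribute a Jensen-inequality bias of
  σ²/2 to cumulative ratios); the spread of session ratios seen between
  participants — wear position, skin optics, fit — is physically a
  between-person effect, and it is what the TOST's σ_log refers to;
* `ε_t ~ N(0, noise_sd_log²)` — per-sample multiplicative noise;
* artifacts — a Poisson number of fixed-duration segments per hour where
  the last valid value is held (a frozen counter registers no increments),
  the simplest model that exercises the epoch-validity logic;
* label misclassification — the activity stream is drawn one categorical
  draw per contiguous `label_dwell_s` block (default 5 s) from the true
  class's row of a 4×4 row-stochastic confusion matrix. Blockwise draws
  were chosen over per-second draws plus run-length smoothing because
  smoothing distorts the marginal misclassification probabilities; blocks
  give contiguous misclassified segments *and* exactly the configured
  marginals, which is what makes the confusion-recovery test meaningful.
  The default matrix is `published_confusion_matrix()` (diagonals 99.3,
  94.2, 89.9, 91.6%). Gait-ambiguous activities (the cross trainer), which
  are masked from scoring, are emitted from the walk row.

With identity models on both sides the device traces equal the reference
traces sample for sample, so every downstream statistic is exact — the
end-to-end identity test asserts ME = MAE = MAPE = 0, coverage = 100%, an
identity confusion matrix and equivalence on all outcomes.

**What the simulator does not emulate:** raw PPG/accelerometer waveforms,
ECG morphology, temperature effects on optical sensors, clock drift between
devices (the protocol is marker-timed), or the device's proprietary
free-living resting-HR selection (only ground-truth annotations are
provided). Passing tests on synthetic data therefore demonstrate the
*statistical pipeline* is correct and calibrated — not that any particular
physical device meets its margins.

## Activity scoring and steps

Reference labels come from the schedule: treadmill (both grades) and
outdoor walking are `walk`; ergometer and outdoor cycling are `cycle`;
outdoor running is `run`; rest, household, desk work, lying and standing
are `other`. The cross trainer is excluded from scoring (it is legitimately
walking-or-running depending on intensity). Whether the inter-activity
rests should be scored at all is not knowable from a protocol description
alone; they are masked by default (`score_rests = FALSE`) so that only
annotated laboratory activities count, and scoring them as `other` is one
flag away. The cohort matrix is the unweighted mean of per-participant
row-normalized matrices; pooled-second counts are also kept in the result.
Overall accuracy is the support-weighted diagonal.

Step counts are read off the cumulative counters at interval boundaries
(value just before the end minus just before the start), per gait activity
and summed over the four walking/running activities for the combined row.

## Exclusions and the pipeline

`study_exclusion_ledger()` encodes the emulated trial's per-analysis
exclusions as *data*, not code: whole-participant rows (adverse events,
reference-device malfunctions, an invalid heart-rate log) and one partial
row (a mis-executed treadmill bout, which masks that activity from the
step analysis without removing the participant). Applied to the
29-participant manifest this yields n = 26 for energy expenditure and
n = 23 for both heart-rate analyses; the respiration and
activity-recognition counts are ledger-configurable because the source
material reports them inconsistently, and this package deliberately treats
the ledger as editable input. `run_pipeline()` wires everything together
deterministically from a single seed and can serialize a JSON report plus
CSV tables.

Aggregation order follows the per-participant-first convention: error
metrics average within participant before taking cohort mean and SD, and
cohort coverage is the mean of per-participant coverages
(`coverage_mode = "pooled"` pools epochs instead — both are legitimate
readings of a table that prints single values without SDs).

## Problem sizes and tolerances in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to keep
Monte-Carlo error small relative to the assertions while running in
well under a minute each: 10 000 replicates for TOST size at the margins
(three binomial SEs of α), 10 000 for solver power (two SEs of the
target), 1 000 full simulator-to-TOST replicates at 26 participants for
ratio recovery and CI coverage (three SEs), 20 participants for confusion
recovery (four SEs per cell), and 200 random instances per brute-force
oracle comparison. Oracle checks (sliding median, coverage, confusion
counts, step totals) are exact equalities against naive enumerations.

## Known limitations

* The simulator's physiology is deliberately simple (first-order set-point
  dynamics, no intra-activity variability beyond noise); it is a test
  harness, not a physiological model.
* Linear interpolation is a mild low-pass filter; for native 1-Hz data it
  is inert, but heavily irregular recordings deserve inspection before
  trusting epoch means.
* The TOST assumes approximately normal log-differences; with n in the
  twenties the t test is robust, but gross outliers (device dropouts that
  survive into session aggregates) should be caught upstream via the
  exclusion ledger.
* No multiplicity adjustment is applied across the six outcomes, matching
  standard practice for co-primary validation endpoints reported side by
  side.
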