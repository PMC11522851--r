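---
title: "Methods: overnight oximetry analysis for acute mountain sickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overnight oximetry analysis for acute mountain sickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctox)
```

## The problem

During ascent to high altitude, arterial oxygen saturation falls and
periodic breathing fragments sleep, producing recurrent nocturnal
desaturations. Acute mountain sickness (AMS) is diagnosed clinically from
the Lake Louise score (LLS), a subjective symptom questionnaire, which makes
prospective identification of susceptible individuals difficult. Continuous
overnight pulse oximetry (1 Hz SpO2 and heart rate from a wrist-worn
oximeter) captures the overnight hypoxaemic burden directly, and summary
metrics derived from it — overnight mean SpO2, the oxygen desaturation index
(ODI), hypoxic burden, time below 80% SpO2, and the shape of the saturation
frequency distribution — are candidate objective markers of AMS risk.

`noctox` implements the full analysis chain for such data: artefact
rejection, desaturation-event scoring, distribution metrics, per-night
feature assembly, and the diagnostic statistics that relate those features
to morning AMS status. Because wrist-oximeter expedition datasets are not
generally shareable, the package also contains a calibrated synthetic cohort
generator so that every stage can be exercised, tested and benchmarked
without any device export.

## Artefact rejection

Wrist oximeters lose the pulse signal with movement and cold, emitting
out-of-range sentinel codes (500 on the device family emulated here) or
implausible jumps. Three criteria flag a raw sample as artefact:

1. SpO2 below 30%;
2. SpO2 above 100% (sentinel codes);
3. a deviation of more than 4% from the reference sample.

Criterion 3 needs a reference. Comparing against the *raw* preceding second
would let a single spike cascade: the good sample after a 500 would itself
deviate by hundreds of percentage points. `flag_artefacts()` therefore
compares against the most recent *retained* sample, scanning left to right;
the first sample that survives criteria 1–2 seeds the reference and is
exempt from criterion 3. A corollary, which the test suite asserts on random
traces, is idempotence: re-filtering an already-cleaned series flags
nothing, because every retained pair was already checked against each other.

Flagged samples are removed, never interpolated. The artefact index (AI) is
the percentage of raw samples flagged. Retained samples keep their original
sample times, so windowed operations downstream can refuse to bridge long
gaps. One behaviour worth knowing: a desaturation falling faster than 4%/s
— or an artefact landing mid-slope and removing the reference — can cascade
criterion 3 through the rest of the event. On the synthetic cohort this
inflates the mean AI slightly above the injected corruption rate (about
0.84% realised vs. 0.75% injected); the same interaction exists for any
filter built from these criteria on real steep desaturations.

The rule also has a rarer, harsher failure mode: when the sample that seeds
the reference is itself corrupt but within plausible range (a spike in the
first recorded second), every later sample deviates from the stale
reference and the entire night is discarded. `flag_artefacts()` exposes a
`reset_after` argument that re-seeds the reference after that many
consecutive step-criterion flags, bounding the damage on real recordings;
the default (`Inf`) keeps the plain three-criteria behaviour, which is what
makes filtering exactly idempotent. The synthetic generator does not
produce the pathological seed — device start-up corruption presents as
out-of-range acquisition codes, which criteria 1–2 catch, not as
plausible-range spikes.

## Desaturation events

Event scoring uses a relative criterion suited to altitude, where absolute
thresholds saturate: the rolling baseline at second *t* is the **maximum**
SpO2 over the preceding 20 s of clean signal. The maximum (rather than a
windowed mean) is robust to the ongoing decline contaminating the window.
An event opens when SpO2 drops to at least 4% below baseline, and closes
when SpO2 recovers to within 2% of the baseline recorded at onset. The 2%
hysteresis is the sleep-medicine convention; a pure return-to-baseline rule
truncates events in drifting signal. Events shorter than 10 s are
discarded, consistent with standard desaturation scoring and with the
~18–22 s mean durations seen in expedition recordings. Events may not span
artefact gaps longer than 5 s (area under missing data is undefined), and a
contiguous run must be at least 21 s long to support the baseline window.
All five constants (4%, 20 s, 2%, 10 s, 5 s) are arguments with these
defaults.

Per-night rollups follow the standard definitions: ODI = events per
artefact-free hour; hypoxic burden = total event area (sum of
baseline-minus-SpO2 over event samples, %·s) divided by 60, per
artefact-free hour, i.e. %·min/h. Published tables in this literature are
not always consistent about the burden scale; `noctox` reports exactly the
definition above and makes no attempt to rescale.

```{r events-example}
trace <- c(rep(88, 60), rep(82, 30), rep(88, 510))
clean <- data.frame(elapsed_s = seq_along(trace) - 1, spo2 = trace, hr = NA)
detect_desaturations(clean)
```

## Saturation distributions

`build_distribution()` bins clean samples into integer SpO2 bins 30–100 (the
filter guarantees this range) and reports relative and cumulative
frequencies plus the moments of the *raw* samples — binned midpoints would
add quantisation bias. Kurtosis is reported "proper" (fourth standardised
moment, normal = 3), skewness as the third standardised moment, both without
small-sample bias correction: an overnight recording has tens of thousands
of samples, where the corrections are negligible. The variance field uses
the n−1 denominator by default (matching mainstream statistics packages),
switchable to the population form. With zero variance the standardised
moments are undefined and reported as `NA` with a flag rather than a number.

Time-below metrics summarise the cumulative curve: `time_below(x, 80)` is
TST80, the percentage of clean time strictly below 80%. Strict-below is the
default (an inclusive variant is available), and for integer data
`time_below(t)` equals the cumulative frequency at bin t−1 — an identity the
tests check on random series. Conventional large-sample shape cutoffs are
provided: kurtosis proper above 7 flags a significantly peaked night,
absolute skewness of 2 or more flags substantial asymmetry.

## Per-night features

`night_features()` assembles the feature vector used by the diagnostic
layer: overnight mean ± SD of SpO2, HR and the HR/SpO2 ratio; ΔSpO2 (second
half mean minus first half mean — the halves are split by clean-sample
count, not wall clock, so artefact gaps cannot unbalance them, and with an
odd count the middle sample is excluded, making the statistic exactly
antisymmetric under time reversal); the lowest trailing moving averages at
30 s and 3/15/30/60 min; the first and last 15 clean minutes; event
summaries; distribution moments; TST80; AI and clean duration. Moving
averages are trailing, require full windows, and never span gaps longer
than 5 s — partial or centred windows would blur what "lowest average"
means. Metrics that a short recording cannot support are `NA`
(not-assessable), never silently dropped.

## Diagnostic statistics

A morning is AMS-positive when the LLS total is at least 3 *and* headache
scores at least 1. Mornings with total ≥ 3 but no headache fall outside
both textbook definitions; the conjunctive rule classifies them negative
and marks them `ambiguous` for audit. Nights are the unit of analysis,
each paired with the morning that ends it; repeated measures within
participant are *not* modelled, a deliberate simplification that matches
how such pooled expedition tables are usually presented and is a known
limitation for inference.

Group comparisons use the Mann–Whitney U test with the Hodges–Lehmann
estimate (median of all pairwise AMS+ minus AMS− differences, computed in
memory-bounded chunks) and a 95% CI from inversion of the rank test
(`wilcox.test(conf.int = TRUE)`). Values beyond ±3 SD of a feature are
screened out first (single pass, mean and SD from all values).

ROC analysis evaluates every midpoint threshold, orients the curve so AUC
≥ 0.5 and reports whether positives score *below* or *above* the cutoff.
The operating point maximises sensitivity + specificity, which is the
argmax for both Youden conventions; ties break towards higher sensitivity
(screening favours sensitivity), then towards the cutoff nearest the pooled
median. Both conventions are returned: the standard index
(sens + spec − 1) and the sum convention (sens + spec) that some published
screening tables print — reproducing such tables requires the sum form,
while the literature expects the standard one. The AUC confidence interval
is Hanley–McNeil; the AUC always equals U/(n₁n₂), an identity the tests
verify exhaustively on small cases.

Bland–Altman agreement takes differences as reference − test (capillary
SaO2 minus oximeter SpO2), reports bias and 95% limits of agreement, and
fits differences on averages by OLS; the x-intercept (−b₀/b₁, the
saturation at which the fitted disagreement vanishes) gets a Fieller-type
interval, which is the appropriate (asymmetric) interval for a ratio of
regression coefficients. Exploratory Pearson correlations relate each
night-at-altitude feature to each participant's peak morning LLS total,
pairwise-complete, p-values unadjusted by default with an optional
Benjamini–Hochberg column.

## The synthetic cohort

The generator emulates a 12-night trekking ascent (nights labelled day2 to
day13, ~1150 m rising to a 4800 m top camp held for three nights, with a
repeated camp at 3000 m) by 18 participants, and produces every data stream
the pipeline ingests: 1 Hz session files, morning and evening LLS records,
morning spot readings averaged over a 75 s segment (the midpoint of the
60–90 s display-averaging convention), and capillary SaO2 on four mornings.

Its components, with the reasoning behind the defaults:

* **Mean saturation** interpolates piecewise-linearly between anchors
  (97% at sea level to 83% at 4800 m), plus a stable per-participant offset
  (SD 1.6%) and per-night noise (SD 1%).
* **Desaturation events** are trapezoids (linear fall at 2%/s, plateau at
  the nadir, linear recovery) with truncated-normal depth (mean 7%, min 5%)
  and lognormal plateau duration (median 18 s). The rate rises linearly
  from 1.5/h below 2000 m (the sporadic events of healthy sleep, which also
  give sea-level nights their characteristically peaked, leptokurtic
  distribution) to 40/h at 4800 m, yielding top-camp ODI around 40/h and
  hypoxic burden around 100–120 %·min/h. Setting the ramp rate to `Inf`
  gives square-wave events whose detected area is exactly the analytic
  area — the configuration the detector round-trip suite uses.
* **Slow wandering**: an AR(1) component with a ~30 min time constant whose
  amplitude grows with altitude (0.3% → 1.8%). This is what flattens the
  saturation distribution with ascent (kurtosis proper falling towards ~3
  at the top camp) while baseline nights stay narrow and peaked; fast
  observation noise (AR(1), SD 0.6%) and integer rounding sit on top.
* **AMS structure**: each night is AMS-positive with marginal probability
  0.2; positive nights get a −5% saturation offset, a 1.5× event rate and
  +4.5 beats/min. The per-participant positive rate varies with the
  residual component of a latent symptom susceptibility — the part
  *orthogonal* to the saturation offset. This construction keeps the
  AMS+/AMS− saturation contrast exactly at the configured −5% (labels are
  independent of the offset and of altitude) while still letting peak LLS
  correlate with overnight SpO2 through both the susceptibility-to-score
  mapping and the clustering of −5% nights in symptom-prone participants.
  Coupling the labels to the offset itself would confound the group
  contrast, which the calibration tests pin to the configured effect.
* **LLS scores**: severity = susceptibility + small per-morning noise, then
  mapped to totals (≥3 with headache on positive mornings, ≤2 otherwise,
  so classification from the records always reproduces the generating
  label). With these defaults the correlation between first-3850 m-night
  overnight SpO2 and peak LLS averages about −0.5 across seeds. A mean
  much beyond −0.6 is not attainable at this design: with 18 participants,
  a 0–12 integer score, and a peak taken over twelve mornings, score
  discretisation and the max operation put a ceiling on the achievable
  correlation, and the sampling SD of r at n = 18 is ~0.19, so individual
  seeds legitimately range from roughly −0.8 to −0.2.
* **Artefacts** corrupt each sample independently with probability 0.0075
  (sentinel 500, ±8–25% spikes, sub-30% dropouts), all of which the filter
  criteria catch.
* **Capillary SaO2** is linked to the morning spot reading through a
  difference-vs-average relation (slope 0.55, x-intercept 96.5%) so the
  agreement analysis recovers a proportional-bias pattern: oximeter spot
  readings progressively overread relative to capillary saturation as
  saturation falls.

What the generator does **not** emulate: sleep architecture and arousals,
the waxing–waning cycle structure of periodic breathing (events are placed
with a minimum separation, not a cycle length), mechanistic
chemoreflex/ventilation dynamics, device-specific beat averaging, or
acclimatisation trends within a camp. Passing round-trip tests on this
generator therefore demonstrates correctness of the *scoring rules*, not
validity of any physiological claim about real recordings.

A `summary_only` mode replaces trace synthesis by draws of the night-level
overnight mean from the same model (anchor + offsets + expected event
deficit, plus the analytically-derived share of the slow drift that does
not average out over a night). This is what powers the 500-replicate
parameter-recovery study in the acceptance suite; a consistency test checks
full-trace night means against the summary model.

## Numerical and scale choices

Reproducibility flows from one integer seed: `generate_cohort()` seeds R's
RNG once and draws everything in a fixed order, so a fixed seed reproduces
the dataset exactly; `run_pipeline()` passes its seed to the simulation.
Problem sizes were chosen so the suites are informative yet quick: unit
tests simulate nights of 0.5–2 h (night-level metrics are duration-invariant
in expectation), the detector round-trip uses 100 two-hour nights, the
parameter-recovery study uses 500 summary-mode cohorts at the full 18 × 12
design, and the acceptance script runs the complete pipeline at full scale
(216 nights of ~8 h). Degenerate inputs fail loudly and specifically:
empty sessions, all-flagged recordings, single-class ROC inputs, fewer than
3 Bland–Altman pairs and zero-variance cells all raise typed errors or
return explicit not-assessable markers.

## Known limitations

* Night-level pooling ignores within-participant correlation; p-values in
  the comparison table are anti-conservative to that extent.
* The Fieller interval for the x-intercept is undefined when the slope is
  not significantly different from zero (the bounds are then `NA`).
* The artefact filter's criterion 3 can clip genuinely steep desaturations
  (> 4%/s), slightly inflating AI and deflating event counts; this is a
  property of the published criteria themselves.
* Exploratory correlations are reported unadjusted across cells by design;
  use the Benjamini–Hochberg option when treating them confirmatorily.
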