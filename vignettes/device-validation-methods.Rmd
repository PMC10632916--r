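---
title: "Methods: validating sleep trackers against polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating sleep trackers against polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepconcord)
```

This vignette documents the statistical machinery of `sleepconcord`,
the conventions it fixes where the field leaves choices open, and what
its synthetic test bed does and does not demonstrate about real data.

## Data model and harmonization

A `hypnogram` is an epoch-labelled stage series with a clock anchor.
Epoch `i` (0-based) covers the half-open interval
`[start + i·epoch_len, start + (i+1)·epoch_len)`; epochs are 30 or 60 s.
PSG consensus scoring uses the five-stage vocabulary (W, N1, N2, N3,
REM, plus ART for artifact-scored epochs); contactless devices emit
four stages (W, LS, DS, REM, plus ABSENT for missing or no-presence
epochs). ART and ABSENT are exclusion markers, never sleep or wake, and
map to themselves under every collapse.

Conventions fixed by this package:

* **Stage collapse.** The default reading of device semantics is
  N1, N2 → LS and N3 → DS (`FOUR_DEFAULT`). Because vendors do not
  document their stage definitions, the alternate reading N1 → LS,
  N2, N3 → DS is available as `FOUR_ALT` so its effect on concordance
  can be quantified rather than assumed. Coarser collapses are
  LS, DS → NREM (`THREE`) and all sleep → SLEEP (`TWO`).
* **60 s → 30 s imputation.** A minute-resolution hypnogram is split so
  the first half keeps the minute's own label and the second half takes
  the label of the *next* minute (the last minute duplicates itself).
  The phrase "next adjacent minute" admits a backward reading; we chose
  the forward one as the literal reading and implement it in one place
  (`upsample_to_30s()`) so a dialect switch would be a local change.
* **Grid snapping.** Comparisons live on the reference 30-s grid.
  A test series whose start is within ±15 s of a grid boundary snaps to
  it; larger offsets are treated as clock lag and belong to the
  alignment step.
* **Cropping.** An epoch split by an analysis-period boundary is
  excluded (strict containment), so durations are always integer
  multiples of the epoch length.

## Sleep summary measures

`compute_summary()` yields TST, SOL, WASO, SEFF and stage durations
within an analysis period (AP). Definitional choices:

* **Sleep onset** is the first epoch labelled with *any* sleep stage.
* **WASO** counts all wake from onset to the end of the AP, terminal
  wake included, so wake = SOL + WASO exactly.
* **ART/ABSENT accounting.** Excluded epochs inside the AP count toward
  neither sleep nor wake; they are reported as `artifact_min` and close
  the identity `SOL + TST + WASO + artifact = AP` exactly, for every
  input. Published summary tables typically leave a few minutes of the
  AP unexplained; this explicit artifact term is our resolution of that
  ambiguity.
* **SEFF denominator.** Sleep efficiency is reported as
  `100·TST/AP` by default. Verbal definitions of SEFF often reference
  the total recording time (TRT), but printed cohort tables are usually
  consistent with the AP denominator (e.g. a cohort with TST 422.47 and
  AP 571.75 min printing SEFF 73.86%, whereas TST/TRT would give
  70.4%). Both are available via `seff_denominator`.

## Summary agreement statistics

Differences are device minus reference (`d = y − x`). The Bland–Altman
family uses `bias = mean(d)`, `LOA = bias ± 1.96·SD(d)`, CIs from the
normal approximation (`SE(bias) = SD/√n`, `SE(LOA) = SD·√(3/n)`), and
`MDC = 1.96·SD(d)` — the smallest change distinguishable from
measurement noise at 95% confidence.

Two standardized metrics enable cross-measure, cross-device ranking:

* **SMAPE** `= (100/n) Σ |xᵢ−yᵢ|/(|xᵢ|+|yᵢ|)`. We use the bounded
  variant (0–100%); the common `/2`-denominator variant ranges to 200%
  and is incompatible with a 0–100 scale. Pairs with `x = y = 0`
  contribute zero.
* **SAD** `= mean|d| / sqrt((s²ₓ + s²ᵧ)/2)` — the mean absolute
  difference in units of the average spread of the two raters. It is
  symmetric, dimensionless and invariant to common rescaling; the
  verbal definition "the variance of the reference and test
  measurements" is implemented as the mean of the two sample variances.

Reliability is the consistency intraclass correlation for two raters
under a two-way model, `ICC(C,1) = (MS_rows − MS_err)/(MS_rows +
MS_err)`; it ignores a fixed offset between device and PSG and may be
negative (reported as-is; display layers may suppress). Effect size is
the paired Cohen's *d* `= bias/SD(d)`, classified on |d| as
negligible (<0.1), small (0.1–<0.3), moderate (0.3–<0.5) or large
(≥0.5). A Shapiro–Wilk check on the differences is report-only: no
correction is applied downstream, the flag simply travels with the row.
Satisfactory agreement for stage-duration measures uses published
interscorer ICC thresholds (WASO 0.84, REM 0.75, NREM 0.65, LS 0.67,
DS 0.63), strict inequality.

## Epoch-by-epoch concordance

Pairs are formed on the clock intersection after dropping any pair with
ART or ABSENT on either side ("valid pairs only"). Device clock error
is then estimated by exhaustive search over integer lags in ±10 epochs
(5 min): each lag shifts the test series, re-pairs, and scores
exact-label concordance at the finest common resolution; the
arg-max lag wins, with ties broken toward smaller |lag| and then the
negative lag (preferring the smaller clock correction, and arbitrarily
but deterministically between signs). The lag is chosen per night, not
per device.

Confusion matrices (rows = reference) are built at 2-, 3- and 4-stage
resolution; per-participant matrices sum into pooled matrices. Binary
metrics take sleep as the positive class: sensitivity is sleep
prediction accuracy, specificity wake prediction accuracy. Per-stage
rows (REM, LS, DS at four stages; NREM at three) are one-vs-rest
collapses of the same pairs. MCC is the primary concordance measure
because overnight recordings are heavily imbalanced (roughly 70% sleep
epochs): a device predicting sleep always achieves accuracy ≈ SEFF but
MCC 0. MCC is undefined when a marginal is zero; undefined values
propagate as missing and are excluded from aggregation with a reported
count. Cohort aggregation is mean, SD and the normal-approximation 95%
CI `mean ± 1.96·SD/√n`, clamped to the metric's natural bounds for
display. Satisfactory-concordance thresholds (strict): sleep/wake 0.70,
REM 0.69, NREM 0.48, LS 0.40, DS 0.57.

## Slow-wave activity

`band_power_4s()` splits a single EEG channel into non-overlapping 4-s
windows, tapers with a Hamming window and integrates the one-sided
periodogram over 0.75–4.5 Hz inclusive (bin spacing 0.25 Hz). The
periodogram uses energy normalization `2|Xₖ|²/(N·Σw²)`, which conserves
a tone's power across taper leakage: a 2-Hz tone of amplitude A returns
A²/2 to within the leakage tolerance, a 10-Hz tone contributes under
1%. Since 30/4 = 7.5, windows are assigned to the 30-s epoch containing
their *start*; epochs therefore average 8 or 7 windows alternately, and
trailing windows beyond the last complete epoch are dropped with a
reported count. Overlapping windows or Welch averaging would also be
defensible; non-overlap was chosen for determinism and because epoch
averaging already smooths the estimate.

`ds_swa_regression()` regresses per-participant device deep-sleep
duration on mean NREM SWA (OLS; r² is the squared Pearson correlation).
This asks whether a device's "deep sleep" tracks the continuous
physiological intensity of slow-wave sleep rather than the scored N3
duration alone.

## The synthetic cohort generator

The generator emulates the statistical structure the evaluation
assumes, at the pooled values of an older-adult laboratory cohort under
mild first-night disturbance:

| Parameter | Default | Meaning |
|---|---|---|
| `trt_min` | 600 min | recording span |
| `ap_min_mean/sd` | 543 / 36 min | lights-off period duration |
| `seff_mean/sd` | 0.71 / 0.10 | subject-level sleep efficiency (truncated 0.45–0.95) |
| `stage_props` | N3 .20, N2 .475, N1 .18, REM .144 | stage shares of TST |
| `sol_mean_min` | 15 min | mean sleep-onset latency |
| `sleep_stickiness` | 0.85 | stage persistence; bouts of ~3 min |
| `p_art` | 0.01 | artifact epoch rate |

Mechanics: a first-order Markov chain on 30-s epochs over
{W, N1, N2, N3, REM}. The wake row exits at rate `q = 1/(2·SOL)`;
sleep rows return to wake at the flow-balance rate
`r = q(1−fs)/fs`, which makes the stationary sleep fraction exactly the
subject's target `fs`; conditional on staying asleep the kernel is
`a·I + (1−a)·1πᵀ`, whose stationary law is the configured stage mix for
any stickiness `a`. Two calibration corrections keep the generator's
*realized* moments on its configured values: the stationary target is
inflated for the wake burn-in (the chain starts awake, under-sampling
sleep by ≈ `fs·τ` epochs, `τ` the relaxation time) and for artifact
relabelling; and the subject-level draw SD is deflated by the
analytically expected within-night sampling variance so the realized
cohort SD matches the configured dispersion.

Device observations are generated by per-epoch sampling from a
row-stochastic confusion table (rows = true four-stage labels), then
run-length smoothing, ABSENT-run overlay, a claimed-clock lag, and
optional 60-s re-gridding (majority of the two halves, ties to the
first half — with two halves this reduces to the first half's label).
The built-in presets calibrate each row's sleep mass to published
overall sensitivities and the wake row to published specificities of
four device families; the within-sleep splits are assumptions. The
`ds_coupling_profile()` preset has a deliberately faithful DS row so
that, when the EEG generator couples a subject-level SWA multiplier to
N3 duration at correlation ρ, the DS-vs-SWA regression recovers
r² ≈ ρ² with ρ = 0.77 by default.

What the generator does **not** emulate: ultradian REM cycling and
sleep-cycle architecture; state-dependent device errors (real sensors
fail during movement, i.e. errors correlate with transitions, while the
confusion sampling here is conditionally independent given the stage);
respiratory events; EEG morphology (spindles, 1/f background). Passing
tests therefore demonstrate that the *evaluation machinery* is correct
and that parameters injected at realistic magnitudes are recovered —
not that any real device meets or fails the thresholds.

## Numerical and degenerate-input conventions

* Empty pairings, all-ABSENT device streams, constant inputs to
  correlation/ICC/SAD, and zero-marginal confusion matrices raise
  informative errors or return flagged `NA`s rather than silently
  producing 0s.
* An all-wake night yields TST 0, SEFF 0 and SOL equal to the AP
  duration, flagged `no_sleep`.
* Zero-variance differences collapse the LOA to the bias with
  zero-width CIs (valid, not an error); Cohen's *d* is undefined there.
* All simulation is driven by explicit seeds; cohort generation derives
  per-subject seeds from the master seed, so any night is reproducible
  in isolation.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to make Monte-Carlo tolerances
meaningful while keeping the suite quick: 200 nights for generator
moments, 100 nights for closed-loop confusion recovery, 200 repetitions
of lag recovery on ~900-epoch nights at 20% corruption, 10,000 pairs
for limits-of-agreement coverage, five replicate 17-night cohorts for
the DS–SWA coupling regression, and ≥500 random instances per metric
for oracle equivalence.

## Known limitations

* The analysis-period error model shifts the lights-off interval
  deterministically per profile; real automatic detection errors vary
  night to night.
* Actigraphy-like devices are expressed in the same confusion-table
  formalism; the underlying activity-count thresholding is not
  simulated mechanistically.
* The consistency ICC assumes the two-way model is sensible for n of a
  few dozen; with very small n the estimate is unstable, which is why
  CIs and the MDC travel alongside it.
* Cohen's κ is intentionally absent: MCC plays its role and is nearly
  identical to κ on the positive quadrant while remaining defined under
  extreme imbalance.
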