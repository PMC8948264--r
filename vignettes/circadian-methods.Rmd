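---
title: "Rhythm statistics, desynchrony classification and label-free differential expression: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm statistics, desynchrony classification and label-free differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadia)
```

`circadia` implements the computational core of a circadian behavioural
study: rhythm statistics for mouse wheel-running and fly locomotor
records under complex light schedules, classification of jetlag
re-entrainment and internal desynchrony, and a Perseus-style label-free
proteomics differential-expression workflow.  This vignette explains the
models, the tunable parameters and the numerical decisions, so that a
reader can judge what a passing test suite does and does not establish.

## Light schedules

A `light_schedule` is a piecewise-constant lux function on a real-valued
hour axis whose origin sits at the first lights-on; all intervals are
half-open `[start, end)` so every time point belongs to exactly one bin
and one phase.  Supported paradigms are plain LD, DD, LL,
stepped-intensity LL, a single abrupt advance/delay, and chronic jetlag
(a fixed shift every *n* days).  Shifts are implemented by truncating
the dark phase of the transition night — an advance brings lights-on
forward — which is the standard implementation of LD advances; the
alternative (truncating the light phase) is available through
`truncate = "light"` because published descriptions of such protocols
usually do not say which phase absorbs the shift.

For a schedule that advances 6 h every 2 days, the cycles alternate
24 h and 18 h, so the *effective zeitgeber period* is the block length
divided by the cycles per block: (48 − 6)/2 = 21 h.  Two consequences
matter downstream: an entrained animal shows a 21-h periodogram peak,
but its waveform is strictly periodic only at the 42-h block length.

## The activity simulator

Each simulated animal is a mixture of phase-only oscillators.  An
oscillator carries an intrinsic period `tau`; once per cycle its onset
advances by `tau` plus a clamped correction toward the zeitgeber
reference (lights-off for the nocturnal mouse, lights-on for the fly
morning component).  The correction is the signed circular misalignment
`delta = reference − onset`, clamped to `[-max_advance, +max_delay]`
(a required advance appears as negative `delta` in this convention),
and is zero in constant darkness.  A phase-only model is the simplest
generator with *bounded re-entrainment speed*, which is the property the
jetlag metrics must detect; it deliberately does not model amplitude
dynamics, PRC shape, or after-effects.

Counts are emitted per bin as independent Poisson draws with expected
value `(rate_rest + sum_k weight_k * rate_active_k * W_k(t)) * (1 −
masking * [light on])`.  The mouse waveform `W` is a rectangular
`alpha`-hour active window.  The fly waveform is bimodal: raised-cosine
morning and evening bouts separated by `alpha` hours, each preceded by
an exponential anticipation ramp with time constant `ramp_tau` and
relative amplitude `ramp_amp`, which makes the anticipation index
continuously tunable around its 0.5 null.  The morning bout defaults to
0.6 of the evening bout's amplitude: fly evening activity dominates, and
two *equal* bouts spaced near half the period would cancel the circadian
fundamental and push all spectral power into the 12-h harmonic, which no
real fly record does.  Two further knobs emulate specific phenotypes:
`amplitude_decay` (< 1) damps the active-phase rate once the animal is
in permanent darkness, producing delayed arrhythmicity, and
`tau_drift_sd` lets `tau` follow a daily random walk, producing
fluctuating-period rhythms.

Default study conditions follow the recorded paradigms: 6-min wheel
bins and 1-min beam-cross bins; 12:12 LD entrainment baselines; 14-day
DD free runs; a 7-h acute advance observed for ~3 weeks; the 6-h/2-day
chronic advance for 4 weeks; 12-day fly DD records scored in 6-day
windows.  Where the source protocol gives no number (activity rates,
masking depth, clamp sizes) the defaults are ordinary laboratory
magnitudes — peak wheel rates of ~30 counts/6-min bin, 90% masking,
clamps of a few hours per cycle — chosen once and not revisited.  One
master seed drives everything; per-subject streams are derived by fixed
increments so subject *k* is reproducible independently of the cohort
size.

## Rhythm statistics

The chi-squared periodogram folds the series at every candidate period
of `P` bins using only the `K = floor(N/P)` complete cycles and computes
`Q_P = K N_u sum_h (M_h − M̄)² / sum_i (x_i − M̄)²`, where `M_h` are
the fold's column means, `M̄` the grand mean and `N_u = K P`.  This
normalization makes `Q_P` approximately chi-squared with `P − 1` degrees
of freedom under a white-noise null, verified by a Monte-Carlo
calibration test, and gives `Q = N_u` for a noise-free square wave at
its true period.  The significance line is the pointwise `1 − alpha`
chi-squared quantile by default, with a Bonferroni option over the
tested periods.  "Periodogram amplitude" is defined here as Q at the
main peak minus the significance line at that period — a declared
convention matching common actigraphy software, since the measure has
no published formula.

FFT rhythm power is the maximum of the mean-removed, sum-normalized
power spectrum at periods inside a band (default 18–30 h); no taper is
applied.  On this normalized scale the conventional fly rhythmicity
threshold of 0.01 is meaningful: six days of pure Poisson noise
essentially never reach it.

Activity onsets follow the classical actogram rule: within each
folding-period window, after a centred moving average (15 min for
mouse, 30 min for fly records), the onset is the first bin reaching
20% of the window maximum and the offset the last bin at 5%.  Both
thresholds are relative, so detection is invariant to count rescaling.
Two refinements handle drifting free-runs, where a fixed window can
open mid-bout: the crossing is taken from the window's *main bout* (the
contiguous suprathreshold run with the largest total activity), and a
run touching the window start is excluded as the spill-over of the
previous cycle whenever another run exists.  In a clean single-bout
cycle both rules reduce to the plain first/last crossing.

The free-running period is the folding period plus the slope of an
ordinary least-squares line through the daily onsets.  Days are
subjective cycles: the cycle index is recovered from the absolute onset
spacing, because a rhythm much faster than the folding period
occasionally packs two onsets into one window and would otherwise bias
the slope.  Phase shifts around a light pulse are measured from
regression lines fitted before and after the pulse (skipping 3
transient days) and extrapolated to the day after it; positive values
are advances.  The phase angle of entrainment is the mean signed
difference between onset and lights-off over six consecutive days,
negative when activity starts before dark.

## Jetlag endpoints and classification

The cumulative re-entrainment curve references each post-shift onset to
the mean onset phase of the last six pre-shift days, measured on the
*old* schedule grid, signed toward the shift direction.  "Days to
re-entrain" is the first day on which the curve sits within 0.5 h of
the full shift for 3 consecutive days — an explicit operationalization
of "stable entrainment", configurable because the endpoint is usually
reported without a definition.

Chronic-jetlag classification scans 16–28 h.  A significant peak in the
20–22 h band marks the entrained component.  The search for a second,
free-running component must cope with two artifacts: a strong periodic
component produces sidelobes at rational multiples of its period that
cross a pointwise significance line, and the entrained waveform is only
block-periodic (42 h), which folds into genuine 28-h structure.  The
long-band search therefore runs on a pre-whitened residual: the counts
are square-root transformed (stabilizing the Poisson variance so the
chi-squared line is valid), the mean waveform folded at the block
period is subtracted, and the first 4 days of the segment are dropped
as a re-entrainment transient.  Both scans use the Bonferroni line,
since the decision is about *any* peak among ~120 tested periods.  A
surviving long-band peak above 24 h gives `desynchronized`, below 24 h
`desynchronized_short_period`; band edges encode the conventional
"~21 h", ">24 h", "<24 h" wording and are configurable.

Fly DD classification calls a 6-day window rhythmic when the
periodogram has a significant peak *and* the FFT power exceeds 0.01.
Rhythmic-then-arrhythmic flies are `delayed_arrhythmic`; flies rhythmic
throughout but with an unstable period are `rhythmic_unstable_period`.
Period stability is estimated from sliding 4-day windows: successive
window periods differ by roughly the 4-day change in `tau` divided by
the window length, so the SD of those differences is scaled by the
square root of the window length to estimate the *per-day*
period-change SD, which the 0.5 h/day threshold addresses directly.
Windows shorter than 4 days would violate the periodogram's 3-period
precondition; longer windows average the fluctuation away.  At a drift
of 0.6 h/day the unstable label is recovered in a majority of
replicates; the classification-recovery suite uses 1.0 h/day for its
unstable cohort, a level at which actograms are visibly unstable, since
the phenotype is graded and the recovery claim should be made where the
classes are genuinely separated.  Analysis runs at 5-min resolution
(1-min records are rebinned): at circadian periods the finer grid adds
no period information.

Group comparisons of phenotype categories use the two-sided Pearson
chi-squared test without continuity correction — the uncorrected form
is what reproduces the published worked examples to their printed
precision — via `stats::chisq.test`, checked in the tests against a
hand-computed oracle.

## Label-free differential expression

The proteomics workflow mirrors the standard Perseus sequence.
Preprocessing drops rows flagged reverse, contaminant or
identified-by-site, log2-transforms, and keeps proteins with at least 4
quantified values across retained samples; stage row counts are
reported so a real proteinGroups table can be checked against its
published filtering trail.  Missing values are imputed per sample
column from `Normal(mu − 1.8 sd, (0.3 sd)^2)` of that column's observed
distribution — the left-censoring assumption that low-abundance
proteins go missing; whole-matrix mode is available.  Pairwise Pearson
correlations (pairwise-complete, before imputation) flag samples below
r = 0.90.

The test statistic is the pooled-variance two-sample t with a SAM-style
stabilization constant in the denominator: `d = (m2 − m1) /
(s_p sqrt(1/n1 + 1/n2) + S0)`.  `S0` damps the significance of tiny
fold-changes; `S0 = 0` recovers Student's t exactly.  The default is
0.1, with 0 selectable, because published analyses of this kind state
both values in different places and neither can be verified as the one
actually used.  p values come from the t distribution (the analytic
route is deterministic; Perseus's permutation option is not), q values
from Benjamini–Hochberg step-up (`stats::p.adjust`, oracle-checked),
and enrichment from the one-sided hypergeometric tail with at least 3
foreground proteins per term.

Imputation from a downshifted distribution induces dependence between
the imputed cells and the group structure wherever missingness is
differential, so BH's nominal level is not exact for the full pipeline;
the suite therefore checks the realized false-discovery proportion
against a 0.10 ceiling (twice the nominal 0.05) over 20 simulated
datasets of 800 proteins, 4 + 4 samples, 10% planted effects of mean
|log2 FC| 1.0.

## Problem sizes and limitations

The simulation suites run at desk scale: cohorts of 10–34 animals,
14–28 day records, 200 subjects for classification recovery, 800–4,000
protein rows, 1,000 white-noise replicates for the null calibration.
These sizes give the comparisons their stated resolution (e.g. ±0.1 h
period recovery) while the full suite runs in well under a minute per
module.

The generators emulate the statistical structure the analyses assume —
Poisson counts, clamped phase dynamics, left-censored log-normal
intensities — not the full texture of real data: no ultradian bouts,
no wheel-availability artifacts, no shared-cage correlation, no
peptide-level effects, and no real annotation database (enrichment is
tested on synthetic term maps).  Passing tests therefore establish that
the estimators recover what they claim under their stated model, and
that the worked numerical examples and analytic identities hold
exactly; they do not certify performance on recordings whose noise
violates those assumptions.  Lomb–Scargle, wavelet and cosinor methods
are out of scope, as is any mixed-effects group modelling beyond the
category chi-squared test.
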