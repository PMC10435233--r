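---
title: "Models and methods behind optophysio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optophysio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optophysio)
```

## What the package computes

`optophysio` quantifies optogenetic manipulation experiments in larval
zebrafish from video-derived time series. Its analysis stages are:

1. **Signal extraction** — mean ROI luminosity per frame from grayscale
   stacks, delta-F/F normalization of calcium traces, and relative heart
   area from automatic segmentation.
2. **Cardiac analysis** — heartbeat detection from the luminosity trace,
   relative heartbeat frequency, cardiac arrest latency / time to
   resumption, arrest-time ratios across trials, and atrioventricular (AV)
   conduction delay.
3. **Locomotion analysis** — tail-bout detection from lateral-displacement
   traces and the four trial metrics: induction, latency, duration and
   strength, plus the locomotion-inhibition readout.
4. **Aggregation** — per-larva averaging, group mean ± SEM, Wilcoxon
   rank-sum and one-way ANOVA + Tukey comparisons.

Because assays of this kind are typically scored on videos that are never
deposited, the package ships a **synthetic-data generator** whose planted
ground truth makes every stage testable by parameter recovery. The
generator is first-class, tested code, not a fixture.

## The photostate model

Bistable opsins sit in either a dark (inactive) state or an active
photoproduct state. Light drives both directions — activation at one band,
photoreversal at another — and a light-independent *adaptation* pathway
returns the active state to rest. The generator integrates the active
fraction $a(t) \in [0,1]$ under a piecewise-constant light schedule:

$$\frac{da}{dt} = k_{act}\,\sigma_{act}(\lambda)\, I\,(1-a)
  \;-\; \bigl[k_{rev}\,\sigma_{rev}(\lambda)\, I + k_{adapt}\bigr]\,a$$

with $I$ the irradiance (mW/mm²) and $\sigma(\lambda)$ unit-height Gaussian
spectral-efficiency bumps. Within each constant-light segment the equation
is linear with constant coefficients, so the integrator advances by the
exact exponential update between output samples (splitting steps at segment
boundaries). There is no step-size error; the tests verify agreement with
the global closed form to much better than $10^{-6}$ relative error and the
bound $a \in [0,1]$ on randomized schedules.

No quantitative photocycle constants are published for these tools, so the
preset magnitudes (`opsin_regime()`) are free generator parameters. They
were fixed once so that the standard protocol — a 1 s pulse at 0.5 mW/mm²
— plants arrest latencies around 0.8–1.0 s and resumption times around
5–12 s, the scale reported for the three cardiac tools, and so that the
presets preserve two qualitative orderings: the switchable violet-activated
regime has a spectrally separated reversal band (so sustained ~470 nm
light shuts it off), while the green-activated regime does not. A single
adaptation constant cannot simultaneously reproduce the ordering of
dark-recovery times *and* the ordering of recovery under prolonged
activating light reported for these tools; the presets follow the
dark-recovery (resumption) ordering, and the switchable behaviour comes
from photoreversal, which is the mechanism the downstream contrast tests
actually exercise.

## The heart simulator

Beats are generated by phase accumulation: the instantaneous rate (bpm) is

$$r(t) = r_0 \,\bigl[1 - \min(a/\theta, 1)^{p}\bigr]\; g(t)$$

where $\theta$ is the arrest threshold (`arrest_threshold`, default 0.5)
and a beat is emitted at every unit crossing of $\int r/60\,dt$. The gate
exponent $p$ (default 4) keeps the rate near baseline until $a$ approaches
the threshold: with a linear gate ($p=1$) the rate sags so early during the
photostate rise that planted latencies land near 0.45 s and the slowed
pre-arrest beats themselves create spurious long gaps; the sharper gate
reproduces the observed phenomenology — abrupt arrest within roughly one
beat — while recovery stays graded. $g(t)$ is a first-order relaxation
($1-e^{-\Delta t/\tau}$, `recovery_tau_s` = 3 s) applied after each
suppressed episode, so heartbeats resume sparsely and approach baseline over
tens of seconds.

Each beat is rendered as a raised-cosine luminosity pulse (120 ms wide,
only the peak time matters downstream); the ventricular train is the atrial
train shifted by the AV delay (default 80 ms); Gaussian noise is added per
sample under a mandatory, recorded seed. Cohort simulations add lognormal
per-larva (sdlog 0.15) and per-trial (sdlog 0.05) sensitivity multipliers —
a stand-in for expression-level variability — plus a uniform random beat
phase per trial. The camera frame rate defaults to 67 fps, matching the
instrument class the assay was designed around.

**Ground-truth arrest metrics.** "Arrest onset" is a convention, not an
observable: the generator and the detector share one definition
(`arrest_metrics_from_beats()`): the first post-stimulus inter-beat gap
longer than `gap_factor` (default 2) baseline inter-beat intervals marks
arrest, onset is the last beat before that gap plus one baseline interval
(the first missed expected beat), and resumption is the next beat. The
generator applies the rule to the *planted* continuous beat times; the
detector applies it to beats estimated from pixels or traces. Recovery
error therefore isolates exactly the detection chain.

## Detection choices

* **Beat detection** (`detect_beats()`): running-median detrend (~1 s
  window, "constant" end rule so edge beats are not absorbed into the
  baseline), a short centered running mean (60 ms, symmetric — peak
  positions do not shift), then peak picking with a minimum inter-beat
  interval (default 0.25 s) and a prominence floor: the larger of
  `prominence_frac` (0.5) times the robust beat amplitude (98th percentile
  of |detrended|) and 4 robust noise SDs (MAD of the quiet half of the
  signal). The signal is padded below its floor before peak picking so
  beats truncated at the record edges still register. A flat trace returns
  zero beats rather than an error.
* **Relative frequency** (`relative_hb_frequency()`): beat count in the
  closed window $[t-h, t+h]$ over $2h$, normalized by the mean over a
  pre-stimulus baseline. The half-width default is 0.5 s; a 1 s half-width
  — the other convention in circulation for this assay — is one argument
  away. Boundary beats count once; windows extending beyond the record are
  `NA`.
* **AV delay** (`av_delay()`): one-to-one, nearest-subsequent, non-crossing
  matching of each atrial peak to the earliest ventricular peak before the
  next atrial peak; pairs with delay above 0.5 s are counted and excluded.
* **Bout detection** (`detect_bouts()`): a centered rolling maximum of
  |displacement| over 150 ms bridges the within-bout tail-beat oscillation;
  sub-threshold gaps shorter than 100 ms are merged; bout edges are then
  refined to the raw threshold crossings, because the rolling maximum alone
  would bias onsets early by half its window — directly visible as a
  5-frame latency bias before the refinement was added. Threshold default
  is 0.05 body lengths.
* **Trial classification** (`classify_trial()`): pure rule — a trial is
  excluded if any bout starts pre-stimulus, induced if the first
  post-stimulus bout starts within 8 s; latency/duration/strength come from
  that bout. `locomotion_rate()` is 100 × induced / counted trials.

## Delta-F/F conventions

`compute_dff()` returns $(F-F_0)/F_0$ under three baseline conventions:
the value at the stimulus-onset sample, the mean over a pre-stimulus window
(default 2 s — the source assays do not state a length), or the mean over a
user-marked post-resumption steady-state window. The quantity is the
fractional change (zero at baseline), not the raw ratio (one at baseline):
figure axes in this literature are labelled ΔF/F and plotted around zero
even where the text says "divided by". The convention and the resolved
$F_0$ are recorded on the output.

Heart-area dynamics (`measure_heart_area()`) use an automatic surrogate for
what is usually manual outlining: Otsu threshold computed once from the
temporal-mean image (per-frame thresholds would track the pulsing fill
intensity and flip between structures), applied to a temporally smoothed
stack, keeping the largest connected component. The ratio is taken to the
frame nearest the arrest onset and is exactly 1 there by construction.

## Statistics

Between-group comparisons use the two-sided Wilcoxon rank-sum test, exact
when the combined n is at most 20 with no ties (the regimes here have n = 4
larvae per group) and normal-approximated with tie correction otherwise; an
enumeration oracle in the tests checks the exact branch over all group
sizes with combined n ≤ 10. Multi-group comparisons use one-way ANOVA with
Tukey HSD (studentized range); with two groups the Tukey p equals the
pooled-variance t-test p, which the tests verify. Per-larva averaging
precedes all group statistics, and excluded trials leave the denominator.
Linear mixed-effects analyses are out of scope: the pipeline exports tidy
per-trial tables for external fitting instead.

## What the synthetic data does and does not emulate

The generator reproduces: beat-locked luminosity oscillation with arrest
and graded recovery, paired atrium/ventricle traces with a fixed conduction
lag, beat-coupled calcium transients with an arrest-coupled dip, discrete
constant-amplitude tail bouts in noise, and pulsating two-ellipse frame
stacks whose ROI means reproduce the input traces up to affine scaling
(`render_heart_frames()`, round-trip correlation > 0.99 noiseless). It does
not emulate: photon/camera noise statistics, motion or focus drift,
within-bout amplitude envelopes or swim-style kinematics, pacemaker
variability beyond the sensitivity multipliers, or any biophysical
GIRK-conductance mechanism — suppression is phenomenological by design.
Passing recovery tests therefore demonstrates that the detection chain is
correct and unbiased at realistic noise levels, not that it is robust to
every artifact of real video.

## Problem sizes and numerical details

The shipped analyses and tests use scaled cohorts chosen as the smallest
sizes that exercise every code path with stable statistics: 4 larvae × 6
trials per cardiac regime at 67 fps and 40 s per trial (the standard
design for this assay class), 100-seed noise sweeps for beat/arrest
recovery, 200 trials for locomotion recovery, and 1000 randomized cases
for the classification oracle. Determinism: every generator takes a
mandatory seed; cohorts derive per-trial seeds from a master seed; the
pipeline writes byte-identical CSVs on re-run and stamps each output with
the MD5 hash of the resolved configuration. Degenerate inputs (flat traces,
empty ROIs, baselines ≤ 0, overlapping bouts or schedule segments,
non-uniform sampling) are rejected with explicit messages; a flat cardiac
trace yields an empty beat series rather than an error, and a trial whose
first-trial arrest duration is zero cannot anchor arrest-time ratios.

## Known limitations

* The arrest-onset rule is a reproducible surrogate for visual scoring;
  absolute latencies shift by a fraction of one inter-beat interval if the
  gap factor changes.
* Whether "arrest time" ratios should use duration or latency is ambiguous
  in this assay class; duration is used, which drives post-blockade ratios
  toward 0 and matches the published direction.
* Arrest-time ratios are a skewed statistic: with trial-to-trial duration
  scatter, control-arm ratios have mean above 1 even when nothing changes.
* The photostate magnitudes are not fitted constants; only their
  qualitative orderings and the spectral separations are meaningful.
* ROI means are computed on raw pixel values; background subtraction is
  deliberately not applied.
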