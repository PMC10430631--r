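---
title: "Context-dependent baseline modulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent baseline modulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amygcontext)
```

## Overview

`amygcontext` analyses sessions in which a monkey receives alternating
blocks of two kinds of facial touch: computer-controlled airflow stimuli
delivered in pseudo-random sets over 11 nozzle locations (one of which is a
sham nozzle pointed away from the animal, controlling for sound and
alerting), and grooming sweeps delivered by a familiar human to two facial
locations. The scientific questions the pipeline addresses are (1) which
units respond to the stimuli themselves, (2) which units shift their
*baseline* firing with the block context, (3) how well block context can be
read out from baseline activity alone, and (4) how the autonomic state
(heart rate, respiratory sinus arrhythmia) differs between contexts.

All times are integer milliseconds from session start and every interval is
half-open `[start, end)`, so a spike on a bin edge is counted exactly once.
Spike times are rounded to the nearest millisecond on construction and
post-rounding duplicates collapse to one spike, since a real neuron's
refractory period makes two spikes in the same millisecond implausible.

## The synthetic-session generator

No public recordings accompany this analysis, so the generator is
first-class, tested code: it produces sessions with the statistical
structure the analysis assumes, and every downstream guarantee in the test
suite is a parameter-recovery statement about it.

**Schedule.** The default design is three airflow blocks interleaved with
two grooming blocks. Airflow blocks hold 10 independently permuted sets of
the 11 locations (1-s stimulus, 3-s ISI; a 1-s juice-reward window inside
the ISI after each set). Grooming blocks hold 5 sets of 10 sweeps to
location A then 10 to location B, with sweep durations uniform in 1–2 s and
ISIs uniform in 2–4 s, and a reward window at block end. A config whose
events cannot fit the stated block duration is a scheduling error rather
than a silent truncation.

**Spike trains** are inhomogeneous Poisson: rate(t) = baseline(block kind
at t) + the sum of evoked kernels over events. Two kernel shapes are
provided. `transient_plus_sustained` (typical of airflow responses) is a
rectangular sustained gain from `onset + latency` to stimulus offset plus a
100-ms onset transient at 3× gain. `ramp` (typical of grooming responses,
which track contact pressure) is a triangular profile peaking mid-stimulus
at 2× gain, so its time-average equals the configured gain. The exact
response shapes of real neurons are unknown; these are the simplest shapes
matching the qualitative phenomenology, and nothing downstream depends on
them beyond "there is extra rate inside the stimulus window".

Baseline spikes are drawn per block (exact Poisson count, uniform times)
and evoked spikes per event on a 1-ms discretization of the kernel; sums of
independent Poisson processes give the correct total intensity. A single
master seed keys the session; each unit draws from a sub-stream derived by
a stable polynomial hash of its unit id, so adding a unit never changes
another unit's spikes, and the schedule and EKG use their own sub-streams.

**EKG.** R-wave times come from integrate-to-threshold over the
instantaneous beat rate r(t) = HR(kind)/60 · (1 + depth · sin(2π f t))
(beats/s) with injected tachycardia episodes as additive offsets; a beat is
emitted each time the integral crosses the next integer. This is the
standard mapping from a rate function to a point process. The generator is
deterministic given its spec — the heart model has no stochastic term —
which gives the cleanest analytic limits (constant 100 BPM with zero
modulation depth yields exactly 600-ms IBIs) and suffices to exercise every
consumer; beat-to-beat jitter beyond RSA is a real-data feature the
generator does not emulate. RSA depth and mean HR are configurable per
block kind, since grooming is associated with both a lower heart rate and
deeper RSA.

**What passing tests do not show.** The generator emulates block-dependent
Poisson baselines, additive phasic responses, and sinusoidally modulated
heartbeats. Real data add slow drift within blocks, non-Poisson count
dispersion, correlated variability across simultaneously recorded units,
movement artifacts in the EKG, and imprecise grooming onset times relative
to the pressure trace. Recovery results here therefore bound what the
pipeline can do under its own model assumptions, not what it will achieve
on any recording.

## Responsivity testing

Units enter the analysis when their average rate across the experiment is
at least 1 Hz, they carry a sorting-stability flag, and at least 10 trials
exist per stimulated location. The response test compares per-trial mean
rates in the pre-stimulus window (1000–250 ms before onset) and
post-stimulus window (200 ms after onset to the stimulus' own end) with a
two-sided paired *t* test; a unit responds when p < 0.05 *and* the mean
rate change is at least 1 Hz in magnitude. Three choices deserve note:

* the test is two-sided because suppressed responses count;
* the post window ends at each stimulus' own offset, so variable grooming
  sweep durations give variable windows — rates, not counts, are compared;
* "at least 1 Hz different" is applied to the difference of per-trial
  rate means.

The airflow-vs-grooming label (`airflow_only`, `grooming_only`, `both`,
`none`) considers airflow responses only at groomed locations — responding
to airflow on the posterior head says nothing about a grooming comparison
restricted to the muzzle and brow. Sham responses are scored separately and
never pooled with airflow. Proportions of responsive cells between
conditions are compared with a 2×2 chi-squared test without continuity
correction (a documented flag restores Yates' correction).

The 1-Hz floor makes the test conservative exactly when trials are many
(the *t* criterion alone would then admit sub-Hz changes); with few trials
the significance criterion dominates. The test suite checks both regimes.

## Baseline extraction and context classification

Baseline segments are block time minus a 300-ms buffered window around
every stimulus, minus reward windows; inter-block gaps never enter. The
kept segments are concatenated per block and consecutive full 1-s bins are
cut from the concatenation — segments shorter than 1 s contribute jointly
rather than being discarded — and trailing partial bins are dropped. An
independent brute-force oracle (masking the timeline at 1-ms resolution)
verifies this interval arithmetic on random sessions in the test suite.

The context analysis uses the first two airflow and first two grooming
blocks; any additional block (e.g. airflow with the groomer present) is
reserved for control analyses. Z-scores are computed per unit over the
retained bins of those four blocks jointly and then applied to bins of
further blocks; per-block Z-scoring would erase the very signal under
study. Units need at least 60 bins in each of the four blocks; units short
of that are excluded with a logged reason, not an error.

Cohen's d for independent samples is computed on raw Hz (it is
scale-invariant, so Z-scoring would not change it) for three contrasts:
pooled grooming vs pooled airflow, grooming block 1 vs 2, and airflow
block 1 vs 2. The classification rule — |d_GA| > 0.2 and |d_GA| ≥ 1.5 ×
max(|d_GG|, |d_AA|) — uses absolute values of all three, since the
direction of within-condition drift is irrelevant to the control it
provides. Degenerate input (zero pooled SD) returns 0 when the means agree
and raises otherwise.

The groomer-presence comparison works in raw Hz (not Z), with paired *t*
tests across units on the two steps (groomer-present airflow minus standard
airflow; grooming minus groomer-present airflow), separately for units with
elevated and suppressed grooming baselines.

## Decoding

Per neuron, a linear SVM (regularization constant 1; on 1-D inputs the
accuracy is insensitive to it over a wide range) is cross-validated with 10
stratified folds on class-balanced bins (the majority class is
down-sampled, seeded). Chance is estimated by shuffling the block labels of
the same balanced set and re-running the full cross-validation; the null is
centered on 50% while the true-label accuracy can fall below 50% for weak
units. Significance is accuracy above the 97.5th percentile of the null.
Percentile intervals (2.5/97.5) are used for every 95% interval in the
package.

Population decoding uses pseudo-populations: units come from different
sessions, so no bin correspondence exists, and same-context bins are paired
uniformly at random across units within each bootstrap draw (60 balanced
bins per block by default). For each set size, units are drawn with
replacement (a flag disables replacement), and the criterion accuracy of a
size is the *lower* bound of the percentile interval over draws; the
reported minimum population size is the smallest size whose lower bound
exceeds the threshold (default 95%).

PCA separability projects the bins-by-units matrix onto its first principal
component and scores a 2-means clustering against the true labels, taking
the better of the two label-to-cluster assignments.

Default resampling counts are scaled down (1,000 permutations, 500
bootstrap draws) for interactive use; `run_config(full = TRUE)` restores
10,000 for both.

## Autonomic analysis

IBIs outside the open interval (250, 1500) ms are artifacts; the boundary
values themselves are rejected because their heart rates (240 and 40 BPM)
sit exactly on the stated plausibility edges (a config option widens the
rule to inclusive bounds). Retained instantaneous HR values (60000/IBI,
anchored at each interval's closing beat) are interpolated to a 1-ms grid
with a modified Akima cubic Hermite scheme — the four-secant weighted-slope
rule evaluated through `stats::splinefunH`; this interpolant avoids the
overshoot of ordinary cubic splines across artifact gaps.

The HR series is resampled to 4 Hz before spectral estimation: the analysis
band ends at 0.5 Hz, so a low, even sampling rate loses nothing and keeps
60-s windows at 240 samples (the 1-ms grid is retained for display and
episode detection). Each window is mean-removed and multitapered with K = 7
Slepian tapers at time-bandwidth NW = 4 — the unique pairing consistent
with K = 2NW − 1 and ±0.067 Hz ≤ 0.07 Hz smoothing on a 60-s window. Tapers
are computed as eigenvectors of the standard tridiagonal commuting matrix.
The RSA peak is the largest in-band (0.25–0.5 Hz, i.e. 15–30 breaths/min)
local maximum, ties broken toward lower frequency; strength is the mean PSD
over peak ± half-bandwidth, and windows with no in-band local maximum fall
back to the band mean with the peak flagged absent. Strengths are
normalized as (strength − μ)/μ with μ the *median* across windows, taken as
written in the definition even though μ conventionally denotes a mean; the
median window maps exactly to zero.

High-HR episodes are maximal spans inside grooming blocks with HR above the
stable-period mean + 2 SD for at least 10 s. When no stable period is
supplied, the package takes the longest artifact-free grooming span
(truncated to 20 min) and refines once by dropping milliseconds more than
2 SD from the span's own mean — so an injected tachycardia inside the span
cannot inflate its own detection threshold. Real sessions offer 6–20 min of
stable grooming; synthetic test sessions are shorter, so the minimum
stable-span length is a parameter with a permissive default (1 min).
Grooming responsivity during episodes re-applies the standard response
test to sweeps whose onsets fall inside episodes, pooled across groomed
locations because episode-restricted trials are scarce; fewer than 10 such
sweeps is an explicit insufficient-data outcome.

## The pipeline

`run_all()` chains the stages, logs every excluded unit with its reason,
cross-tabulates effect-size classification against decoder significance
(both / SVM-only / effect-size-only / neither), and writes deterministic
CSV/JSON outputs: all randomness flows from the run seed through named
sub-streams, so identical configurations give byte-identical files. All p
values are raw; no multiple-comparison correction is applied anywhere.

## Problem sizes and numerical tolerances

The test suite runs entirely on synthetic data at sizes chosen to keep a
full run within a coffee break while leaving Monte-Carlo margins well away
from its thresholds: recovery of the 0.5-SD context shift uses 200 units
with 70 one-second bins per block; permutation-null centering uses 1,000
shuffles (mean within 50 ± 2%); the extraction oracle covers 100 random
sessions; end-to-end determinism runs the demo session twice with 100
permutations and 20 bootstrap draws. Spectral recovery is asserted to one
half-bandwidth (±0.067 Hz), the resolution limit the taper design implies.

## Known limitations

* Stability ("stable for N trials") is an externally supplied per-unit
  flag plus the trial-count rule; no drift detection is implemented.
* Airflow duration is 1 s by default but the schema admits up to 1.5 s
  (early-session variant); no per-session flag semantics are attached.
* The generator treats grooming onset times as exact, and its EKG has no
  beat-to-beat noise beyond the configured RSA.
* Decoding is binary (airflow vs grooming) with a linear kernel; temporal
  decoding within stimuli and multi-class designs are out of scope.
* Raw acquisition formats (e.g. Plexon) are not read; sessions enter as
  the documented CSV/JSON directory.
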