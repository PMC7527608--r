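---
title: "Methods: pro-/anti-saccade assessment, saccade detection, and sampling diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pro-/anti-saccade assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisaccade)
```

## The problem

Saccades — the rapid conjugate eye movements that shift gaze between
targets in 30–100 ms at up to ~700°/s — are a sensitive behavioural probe
of neural processing, and their latency, peak velocity and error rate are
routinely altered in neurodegenerative disease. A standardized clinical
paradigm contrasts *pro-saccades* (look at a suddenly appearing lateral
target) with *anti-saccades* (look at the mirror location, which requires
suppressing the reflexive response). This package implements the complete
desk-side half of such an assessment for a 120 Hz binocular head-mounted
eye tracker: protocol generation, log I/O, signal preprocessing, a
five-case velocity-threshold saccade detector, pupillometry summaries, and
diagnostics for the tracker's sampling clock — plus a simulator that
generates gaze logs with known ground truth so every stage is testable
without hardware.

## Session protocol

One session is: 10 pro-saccade practice trials, 60 pro trials, a break,
4 anti practice trials, three blocks of 40 anti trials separated by
breaks, and a final 60 pro trials — 120 non-practice trials per task. Each
trial shows a central white fixation circle for a *fore-period*, then a
red target at ±8° for 1 s (1° diameter, viewed from 7 m; metric positions
follow `d·tan(θ)`). Within every phase the two sides occur equally often
in seeded random order.

The fore-period law states a range, [1, 3.5] s, and a phase mean, 1.5 s,
but not a distribution. We draw uniformly on the range and then apply an
iterated affine shift with re-clipping until the phase mean is exact
(residual < 1e-12 s, absorbed by interior values). This is the simplest
law consistent with both stated constraints; because the mean sits near
the lower bound, the realized distribution is right-skewed with mass near
1 s — any law meeting both constraints must be. Practice trials obey the
same law (the protocol source is silent; uniformity costs nothing).
One RNG, seeded once, drives sides and fore-periods, so a stored seed
reproduces the protocol byte-for-byte — the paradigm fixes one
randomization for all subjects.

```{r protocol, eval = FALSE}
prot <- generate_session_protocol(seed = 1)
table(prot$task[!prot$is_practice])   # pro 120, anti 120
```

## From tracker output to angle

Each frame carries, per eye, a 5-bit validity mask (bit values 1, 2, 4, 8,
16 for gaze origin, gaze direction, pupil diameter, eye openness, pupil
position; 31 = fully valid). Cleaning keeps only mask-31 rows — it never
edits values. The horizontal gaze angle is
`atan(gd_x / gd_z) · 180/π`, negative rightward, positive leftward.
(The source formula as printed multiplies by π/180°, which contradicts its
own prose "radians to degrees" and the ±8° traces; we convert radians to
degrees.) Normalized pupil position x increases rightward from the user's
view, so its sign convention is the mirror of gaze degrees; the detector
inverts the expected sign for that channel.

Spike noise is removed with a running median of order 10, applied to the
whole per-eye stream before segmentation (filtering per-trial would make
window edges depend on the segmentation). An even order forces two
choices the order alone does not determine:

* **Tie-break**: the *lower* median of the 10-value window.
* **Window placement**: an even window cannot be centred. We use
  `[i−4, i+5]`. With the lower median this passes non-decreasing runs
  through with zero lag and leads falling runs by one sample, so across a
  side-balanced design the filter contributes no net latency bias. At the
  series edges windows shrink symmetrically (odd length, true median) —
  no values are invented by padding.

## Velocity: the main unstated numerical choice

Sampling intervals are irregular (warm-up, dropouts), so velocity must be
time-aware. We use two-point differences on actual timestamps,
`v[i] = (x[i+1] − x[i]) / (t[i+1] − t[i])`, assigned to the left sample
(duplicated timestamps dropped first). A centred three-point stencil was
considered and rejected on quantitative grounds: at 120 Hz it averages
over 16.7 ms, which attenuates the velocity peak of a 30–35 ms saccade by
9–12 % — enough to push peak-velocity recovery outside a 5 % band even on
noise-free data. Two-point differences halve the averaging width (≤3.5 %
attenuation at the physiological minimum duration). For an affine signal
both estimators are exact regardless of timestamp jitter.

The remaining grid-phase error (the discrete maximum can fall half a
sample off the true peak) is removed by a quadratic vertex fit through the
peak sample and its two neighbours; the fitted gain is capped at 1.15,
the worst attenuation the fit can legitimately undo, so a degenerate
parabola can never inflate a peak. Latency is deliberately *not*
interpolated below sample resolution — it is reported where the
normalized speed last rises through the onset threshold.

## The five-case detector

Within the task search window (pro: stimulus onset +100 to +500 ms; anti:
+125 to +750 ms; closed bounds), velocity is normalized by its maximum
magnitude and local extrema above 0.5 are candidate saccade peaks, in time
order. The expected primary-saccade sign is negative for a right target
and positive for a left one, inverted for anti-saccade trials (and
inverted again for the pupil-position channel):

* first peak matches the expected sign → **case 1**, or **case 2** if a
  later opposite-sign (return) peak exists;
* first peak mismatches but a later peak matches → **case 3**/**case 4**
  (with return); the first peak is the reflexive response and the
  corrective peak is measured;
* no matching peak → direction **error**; the first peak is measured;
* signal range below 1° (gaze) or 0.001 (pupil position) → **case 5**,
  task not performed: no latency or peak.

Latency is the window-relative time of the first sample of the contiguous
run with normalized speed ≥ 0.25 that ends at the selected peak. Peak
velocity is the signed unnormalized velocity at that peak (gaze channel
only — normalized pupil position has no degree conversion). The
reflexive-response flag is positional and independent of the case logic:
an excursion of more than 3° from the window's initial value toward the
erroneous direction.

Two conventions the source leaves open, fixed here: case-5 trials count as
errors in the error rate (the subject did not perform the task), with the
case-5 count reported separately so the opposite convention is
recoverable; and "both eyes combined" rows pool the per-eye trial results
rather than averaging eye means.

## Sampling-interval diagnostics

Two clocks are recorded per frame: the tracker's integer-millisecond
timestamp and the host's Unix-derived clock. Host-clock intervals are
smoothed with the order-10 running median, device-clock intervals with a
centred moving average of window 5. The *stabilization point* is the first
sustained run (default 50 intervals ≈ 0.4 s) of smoothed intervals
strictly below 8 ms — a single crossing is noise, a run is a regime
change; the run length is exposed as a parameter because the original
criterion was applied by eye. Device-clock intervals are rounded to
integer ms and counted into classes {8, 9, 16, 17, other}: 8/9 is the
8.33 ms frame period split by clock granularity, 16/17 a dropped frame;
no correction is applied. Duplicate frames are consecutive pairs with
identical device timestamp *and* frame sequence: if the payload differs
the pair carries the known SDK timestamp-bug signature, if not it is a
true double read.

## What the simulator states, and what it does not

The generator's defaults are the published group statistics for healthy
young adults measured with this paradigm, so default simulations sit in
the empirically observed regime:

| parameter | pro | anti |
|---|---|---|
| latency (ms) | N(220.40, 43.16²), truncated to the search window | N(343.35, 76.42²) |
| peak velocity (°/s) | N(357.90, 111.99²), truncated positive | N(318.79, 116.69²) |
| direction errors | 0.24 % | 0.66 % |
| reflexive responses | 1.4 % | 13.2 % |

Saccades are raised-cosine position profiles whose analytic peak velocity
and displacement obey `D = (π/2)·A/V`; durations are clipped to the
physiological 30–100 ms band. When a clip fires, primary saccades keep
their drawn peak velocity and grow in amplitude (what the main sequence
does for a fast saccade) because peak velocity is the quantity under
recovery; reflexive, corrective and return movements keep their amplitude
so the trial geometry closes. Reflexive trials prepend a 4° excursion
toward the stimulus that ends 80 ms before the corrective saccade; their
latency draw is truncated from below so the excursion fits inside the
search window — without that, a short-latency reflexive trial cannot
exhibit the reflexive shape at all. Gaze-direction vectors are
back-computed as (sin θ, 0, cos θ) so the arctangent inverts exactly;
per-sample angle noise (0.05° SD, the order of the tracker's spatial
resolution), spikes, validity dropouts, and a per-subject pupil diameter
around 4.3 mm are layered on top.

The sampling clock is a polling loop over a tracker frame queue: capture
on an exact 8.33 ms grid (integer-ms device clock), loop iterations of
9–12 ms during a configurable warm-up (default 25 s, inside the observed
19–28 s band) and 3.9–8.5 ms afterwards, with
`h[j] = max(capture[j], h[j−1] + period[j])`. Warm-up therefore shows
host intervals above the frame period and builds a backlog; when the loop
speeds up the backlog drains at the loop period — this drain *is* the
sub-8 ms stabilization signature — before intervals settle at 8.33 ms.
Two honest consequences: (1) the device-clock smoothed intervals, being
8/9 ms integers, never fall below 8 ms when duplicates are rare, so
device-clock stabilization is reported absent and the criterion is
evaluated on the host clock; (2) recorded host timestamps are read
times, not capture times, so trials scheduled during the drain would
carry biased latencies — the default lead-in (warm-up + 35 s) mirrors the
recommended non-assessment period and keeps trials clear of it.

What a green test does **not** establish: the simulator draws trials
i.i.d. (no within-subject latency autocorrelation or fatigue), pupil
dynamics are a noisy constant (no luminance response), the return saccade
falls outside the analysis windows (so cases 2/4 come from constructed
fixtures, not sessions), there is no blink model beyond validity
dropouts, and no vergence or vertical component. Recovery of the
generating parameters shows the pipeline is unbiased *for this stated
world*, not that the hardware meets specification.

## Numerical choices and degenerate inputs

* Phase-mean correction tolerance 1e-12 s; protocol files store doubles
  with 17 significant digits and round-trip exactly.
* Windows with fewer than 10 samples are marked unanalyzable, never
  silently dropped; `gd_z = 0` samples have undefined direction and are
  removed with a warning; an all-invalid stream is an error, not an empty
  result.
* A window whose velocity is identically zero, or whose range moves but
  shows no supra-threshold extremum, degrades to case 5.
* Ties between equal-magnitude peaks are broken by time (earliest first);
  the last sample of a window never hosts a peak because its velocity
  duplicates its predecessor's.
* The stabilization run length (50) and threshold (8 ms) are parameters;
  lowering the threshold can only delay the detected index.

## Known limitations

Latency carries the detector's intrinsic ~+3 ms threshold-crossing delay
minus the median filter's direction-dependent lead; across balanced
designs these nearly cancel (grand means recover to ≤0.6 %), but
single-trial latencies are only sample-accurate. Peak velocity is
recovered to ≤5 % per trial at 120 Hz; a slower tracker would need the
duration-dependent attenuation model, not a constant correction. The
pupil-position channel yields latency and error rate only. The error-rate
and reflexive statistics at their published per-mille rates need hundreds
of trials before sample proportions stabilize — the package reports exact
arithmetic, not asymptotics.
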