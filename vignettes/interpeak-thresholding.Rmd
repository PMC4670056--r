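---
title: "Classifying coarse-scale behavior from accelerometry with interpeak-minimum thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying coarse-scale behavior from accelerometry with interpeak-minimum thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethopeak)
library(ggplot2)
```

## The problem and the method

Body-mounted tri-axial accelerometers record movement at tens of hertz for
days, but turning those traces into an ethogram — flying, resting on land,
sitting on water; or, for a human, sitting, walking, running — normally
requires either hand-picked, study-specific thresholds or machine-learning
classifiers that are hard to justify biologically. `ethopeak` implements the
histogram-based alternative: derive simple per-second metrics of movement
and posture, plot their frequency histograms, and read the classification
threshold *objectively* off the histogram as the **interpeak frequency
minimum** — the bin of lowest count lying between two modes. Each mode is
taken to correspond to a behavior; the valley between them is where a
threshold misclassifies the fewest seconds, and it is specific to the
individual rather than imported from another study.

Classification is **stepwise**: the most distinct behavior is peeled off
first (flight for a seabird, via the strongly bimodal standard deviation of
heave; sitting for a human, via the first valley of a trimodal histogram),
the histogram is re-examined on the remaining data, and the next behavior is
separated. An optional **bout-averaging constraint** encodes a transition
rule — a cliff-nesting seabird cannot move between land and water without
flying — by replacing per-second pitch with its mean over each segment
between flight bouts before thresholding.

## Per-second metrics

From raw surge/sway/heave samples (units of g throughout) the package
computes, per second:

* moving mean and moving standard deviation of each axis over a centered
  one-second window (25 samples at 25 Hz), sample (n−1) denominator;
* **pitch** `= atan(surge / sqrt(sway^2 + heave^2)) * 180/pi` and **roll**
  `= atan(sway / sqrt(surge^2 + heave^2)) * 180/pi`, by default from the
  *static* (smoothed) components so they reflect posture rather than
  per-sample jitter (`angles = "raw"` is available);
* **ODBA** and **VeDBA**: the L1 and L2 norms of the dynamic components
  (raw minus static per axis). For every sample
  `vedba <= odba <= sqrt(3) * vedba`.

Two readings of "calculated to 1-second intervals" are possible; the default
computes full rolling statistics at every sample and takes the value at each
whole-second tick, which matches the "moving window" description while
yielding one row per second. `mode = "block"` computes non-overlapping
one-second blocks instead. Edge seconds whose full window would leave the
series carry the nearest fully-defined value, so the metric table stays
aligned with raw time and no seconds are dropped. The window length is
`round(sample_rate)` samples, so the same code serves 25 Hz and 40 Hz
recordings.

## Finding peaks and the interpeak minimum

The original description of the method identifies peaks by eye; a tool needs
an operational rule, and this is the one genuinely open design area of the
package. The rule used:

1. counts are smoothed with a centered 3-bin moving mean, *for detection
   only*;
2. every local maximum of the smoothed counts is scored by **topographic
   prominence** — its height above the deeper of the two valley minima
   separating it from higher ground, with the histogram edges treated as
   unbounded descent;
3. maxima with prominence below 5% of the global maximum are dropped, and
   the `expected_k` most prominent maxima at least 3 bins apart are kept.

Prominence, rather than raw height, is what makes detection behave like an
eye across bin widths: at fine bin widths a single behavioral mode breaks
into lumps, and a lump riding on a mode has a shallow saddle and low
prominence no matter how tall it is, so it can never displace a genuine
second mode. All three constants (smoothing span, separation, prominence
floor) are exposed as arguments of `find_peaks()`.

The interpeak minimum itself is then taken on the **raw** (unsmoothed)
counts, strictly between the two flanking peaks. Conventions fixed for
reproducibility:

* ties between equal-count interior bins go to the lowest bin;
* the threshold is the **right edge** of the minimum bin, so the sparse
  valley bin itself falls below threshold;
* at assignment time a value exactly equal to the threshold goes to the
  *above* side, consistent with the right-edge convention;
* histogram bins are left-closed, right-open, with default widths of 0.02 g
  for acceleration-derived metrics and 1 degree for angles (the validation
  grid steps below match these).

The choice of edge is deliberately non-critical: accuracy as a function of
threshold is flat across the valley (see the sweep results the acceptance
script computes), which is also why the method tolerates bin widths varying
over more than an order of magnitude.

## Stepwise plans

A `classification_plan()` is an ordered list of steps; each step names a
metric, the expected number of modes, which interpeak gap supplies the
threshold, and the labels on either side. The assignment *direction* (which
side is which behavior) is always declared, never inferred — it is domain
knowledge, not something a histogram can supply. Two scopes control the
threshold histogram:

* `histogram_scope = "eligible"` (default): the histogram uses only seconds
  still eligible for the step, i.e. data already assigned to earlier
  behaviors are removed before re-histogramming. This is how the land/water
  pitch threshold is found after flight is removed.
* `histogram_scope = "all"`: the histogram uses the full deployment. This
  serves plans whose single trimodal histogram supplies several thresholds —
  the human plan takes both its thresholds (gap 1 and gap 2) from the full
  SD-of-heave histogram, because once sitting is removed the remaining data
  no longer shows three modes and "the gap between the second and third
  peak" would be undefined.

A step may carry a `bout_constraint(anchor)`. Its segments are the maximal
runs of non-anchor seconds (including the stretches before the first and
after the last anchor bout — leaving those un-averaged would leave the
transition rule unenforced at the recording edges), and the step's metric is
replaced by its segment means before thresholding. The threshold, however,
is always computed from the *un-averaged* histogram: averaging sharpens the
separation of the modes but the objective valley is located before that
sharpening. Anchor bouts of any length count by default
(`min_bout_seconds = 1`), because even a brief flight legitimately separates
a land period from a water period; the parameter exists for sensors or
species where one-second anchor blips are noise.

## Validation

`threshold_sweep()` re-assigns the two behaviors at every candidate
threshold on a uniform grid (defaulting to the histogram bin width), scores
each against known labels as the percentage of seconds assigned correctly
(micro accuracy), and reports the brute-force best threshold (ties to the
lowest), the accuracy at the objective interpeak threshold, and the width of
the contiguous plateau with accuracy at or above 95%. The interesting
quantities are the *gap* between interpeak and best accuracy (how much is
lost by not iterating over thresholds — small gaps justify using the
objective threshold where no validation data exist) and the plateau
widening produced by bout averaging. Ground truth can come from recorded
activities, or for on-water behavior from a salt-water immersion logger via
`immersion_to_truth()`: any epoch with an immersion value at or above 1 (of
200) counts as wet by default, a deliberately conservative cut-off exposed
as `wet_min`.

```{r example, eval = FALSE}
sim <- generate_accel(default_kittiwake_spec(seed = 1))
m <- compute_metrics(sim$accel)
res <- run_plan(m, kittiwake_plan())
glance(res)                         # per-step thresholds
accuracy(tidy(res)$label, sim$truth$label)
autoplot(res$thresholds[[1]])       # histogram, peaks, threshold
bc <- bout_averaging_comparison(m, kittiwake_plan(), sim$truth$label,
                                -10, 40, 1)
autoplot(bc)                        # raw vs bout-averaged sweep
```

## The synthetic generator

Because the field recordings behind the method are not distributable, the
package ships a generator (`generate_accel()`) that emulates exactly the
statistical structure the classifier consumes — and nothing more. Per
scheduled bout, acceleration is gravity rotated by the behavior's base
orientation, plus a posture offset drawn once per bout
(`pitch_jitter_sd`), per-second posture wander (`pitch_wander_sd`), a
heave-axis sinusoid (`osc_amplitude`, `osc_frequency`) standing in for
wingbeats or footfalls, and white noise per axis. The closed form
`sd_heave ~ sqrt(A^2/2 + sigma^2)` makes the mode locations predictable and
testable. Immersion epochs are `round(200 * wet fraction)` per 10-minute
epoch.

The default kittiwake spec is a 2-hour, 25-Hz deployment alternating land
(240–720 s, pitch 25 deg), flight (60–240 s, 0.5 g at 5 Hz) and water
(180–600 s, pitch 5 deg) bouts. Per-bout jitter of 2 deg plus per-second
wander of 5 deg makes the land and water *per-second* pitch distributions
overlap in their tails — deliberately, since that overlap is what motivates
the bout-averaging constraint — while segment means stay far from the
threshold. The default human spec is 5 minutes each of sitting, walking
(0.3 g at 2 Hz) and running (1.0 g at 3 Hz) at 25 Hz, giving three
well-separated SD-of-heave modes. These parameter values were chosen once,
as plausible magnitudes for a ~400 g seabird and a walking/running human,
and define the package's reference test conditions.

What the generator does **not** emulate — and hence what passing tests do
not establish about field data: realistic wing-stroke waveforms (pure
sinusoids have no harmonics), low-frequency baseline drift or device slip,
heterogeneous or rare behaviors outside the schedule, gradual behavioral
transitions (available only as the artificial `transition_blur` crossfade),
and sensor artifacts such as clipping or dropped samples. A mode structure
that is clean in simulation can be smeared or split in real data; the
diagnostics (`autoplot()` on histograms and sweeps) exist precisely so the
histograms are inspected rather than trusted.

## Numerical and degenerate-input conventions

* Sample SD uses the n−1 denominator (so a full-period sinusoid of
  amplitude A in a w-sample window gives `A/sqrt(2) * sqrt(w/(w-1))`).
* An all-zero acceleration vector has undefined orientation; pitch/roll are
  set to 0 with a warning rather than failing mid-stream.
* Samples beyond the +-8 g device range warn but are retained; nothing is
  ever filtered or imputed.
* Non-finite metric values at eligible seconds are labeled `"unassigned"`
  and counted; histogram construction drops non-finite values with a
  message.
* Fewer qualifying modes than expected raises a classed modality error
  naming the step, rather than silently thresholding a unimodal histogram.

## Problem sizes used by the test-suite

The packaged checks run the full pipeline on 20 independent 2-hour
kittiwake simulations and 20 15-minute human simulations, enumerate all
small histograms (interior counts 0–3 up to length 6 and binary patterns up
to length 10, plus 1000 random larger ones) against a brute-force oracle
for the interpeak minimum, and sweep bin widths from 0.005 to 0.1 g and 0.5
to 5 degrees on one fixture. These sizes keep the whole suite around two
minutes while leaving the statistical headroom of the 95% accuracy
thresholds far from the observed values.

## Known limitations

* The method is inherently coarse-scale: behaviors must produce separated
  modes in some metric; behaviors sharing a mode (e.g. two stationary
  postures at similar pitch) cannot be split without a different metric.
* Peak detection constants, though robust across bin widths here, are
  heuristics; histograms from other species should be inspected with
  `autoplot()` before trusting `expected_k`.
* The bout-averaging constraint assumes the anchor behavior is detected
  near-perfectly; a missed anchor bout merges two segments and can flip a
  whole segment's label.
* Accuracy is micro accuracy over seconds; with very unbalanced budgets a
  high overall accuracy can hide poor recall on a rare behavior — the
  per-behavior `accuracy(..., scope = )` exists for that reason.
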