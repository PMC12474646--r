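---
title: "Automated mitoVO2 analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated mitoVO2 analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovo2)
```

## The measurement

Cutaneous protoporphyrin IX oximetry reads mitochondrial oxygen tension
(mitoPO2, mmHg) once per second. To measure mitochondrial oxygen
*consumption* (mitoVO2), local pressure on the probe occludes the
microcirculation ("stop-flow"): oxygen supply stops, mitoPO2 falls, and
the rate of decline reflects consumption. Each stop-flow measurement is
recorded at 1 Hz for about 120 s; a session contains several such
measurements separated by reoxygenation and baseline periods.

`mitovo2` automates the two steps that previously required manual work:

1. a bidirectional LSTM labels every sample of a session trace as
   `start` (first sample of a stop-flow decay), `measurement` (remaining
   decay samples) or `na`, and a deterministic rule engine cleans those
   labels into valid measurement segments;
2. each segment is fitted with a modified Michaelis-Menten oxygen
   disappearance model, whose steepest tangent is the measurement's
   maximal oxygen consumption Vmax; the per-subject mean Vmax is the
   subject's mitoVO2.

## The kinetic model

Under stop-flow the tension obeys

$$\frac{dP}{dt} = -\frac{V_0\,P}{P_{50} + P} + Z\,(P_0 - P)$$

a Michaelis-Menten consumption term plus a diffusive oxygen influx from
the surrounding (still perfused) tissue. The parameters, with units and
their roles:

| parameter | units | meaning | fit bounds |
|---|---|---|---|
| `v0`  | mmHg/s | consumption scale; the initial decline slope after compression | [0, 100] |
| `p50` | mmHg   | tension at half-maximal consumption | [0.1, 50] |
| `p0`  | mmHg   | mean pre-compression tension; drives the influx term | [0, 150] |
| `z`   | 1/s    | diffusive influx coefficient | [0, 1] |

The model is integrated with the classic 4th-order Runge-Kutta scheme,
reported on the requested output grid (default the 1-s sampling
interval). Because the fastest local rate of the vector field is
bounded by $V_0/P_{50} + Z$ — up to ~40/s in stiff corners of the
physiological box, far faster than 1 Hz — each output step is
subdivided internally so that (sub-step × rate) stays at or below 0.1,
keeping the 5th-order local error negligible without any tolerance
knob. A fine-step integration and an adaptive solver serve as oracles
in the test suite (agreement better than $10^{-3}$ mmHg over 60 s
across the box $V_0 \in [1,20]$, $P_{50} \in [0.5,10]$,
$P_0 \in [30,100]$, $Z \in [0,0.3]$). Two further numerical
conventions:

* intermediate Runge-Kutta stages may transiently undershoot zero; the
  consumption term is evaluated on $\max(P, 0)$ and any state below zero
  is clipped to zero and flagged, since a negative oxygen tension has no
  physical meaning and the vector field below zero is otherwise
  undefined;
* trajectories start at `p0` (the fit treats the pre-compression mean as
  the curve's starting level).

Because $|dP/dt|$ is strictly decreasing along a decay started at `p0`,
the steepest tangent of the fitted curve is its initial slope,
$V_{\max} = V_0 P_0 / (P_{50} + P_0)$. `vmax_of_curve()` measures the
steepest per-step slope of whatever curve it is given; `fit_segment()`
evaluates it on a 0.01-s grid so the reported Vmax is the tangent, not a
1-s average (which would understate it by several percent on fast
decays).

## Fitting

`fit_segment()` minimizes the sum of squared differences between the
observed segment and the RK4 trajectory over the four parameters, using
bounded Levenberg-Marquardt least squares (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-8`, up to 200 iterations). Starting values follow
simple recipes: `v0` from the mean of the segment's first three finite
differences, `p0` from the mean of the 10 samples preceding the start,
and generic `p50 = 5` mmHg, `z = 0.01`/s. On non-convergence the fit
restarts from up to three deterministically jittered guesses; a fit is
reported `converged = FALSE` (with a null Vmax) rather than silently
extrapolated. `p50` and `z` trade off on short segments — the contract
is the trajectory and its Vmax, not the individual parameters. One
honest caveat: on very stiff decays (`p50` below ~1 mmHg, tension
collapsing within a couple of samples) the 1-Hz samples no longer pin
down the instantaneous tangent — different parameter sets reproduce the
sampled curve to hundredths of a mmHg while their tangents differ by a
few percent. This is a property of the sampling rate, not of the
optimizer. As a
divergence guard, a fitted Vmax exceeding 1.5 times the largest observed
single-step drop marks the fit as failed.

The fit window is exactly the post-processed segment; pre-start samples
only inform the `p0` starting value.

## The segmenter

The network is the field-standard sequence-to-sequence labeler: each
trace is z-score normalized (per trace, since baselines differ between
subjects while the device is relative-scale stable within a session),
cut into overlapping 250-sample windows at stride 10 (240-sample
overlap), and fed one value per time step to a biLSTM with
`hidden_units` cells per direction, followed by a per-sample linear map
to three class scores and a softmax. Training minimizes per-sample
cross-entropy with Adam. The supported hyperparameter box and defaults:

| hyperparameter | box | default |
|---|---|---|
| hidden units / direction | 50-80 | 55 |
| initial learning rate | 0.001-1 | 0.0137 |
| epochs | 2-4 | 3 |
| mini-batch size (windows) | 60-100 | 80 |

The biLSTM forward pass and backprop-through-time are implemented in
RcppArmadillo inside this package; a finite-difference gradient check in
the test suite validates the analytic gradients to ~1e-6 relative.
Training is seeded end to end (weight initialisation, epoch shuffling),
so the same seed reproduces the same weights bit for bit — the basis of
the pipeline's repeatability guarantee.

Design points that the architecture description leaves open, and how
they are resolved here:

* **Inference on whole traces.** Windowing is a training device; at
  inference the network runs on all stride-10 windows covering the
  trace (plus a clamped tail window) and class probabilities are
  averaged where windows overlap before the per-sample argmax.
* **Short traces** are tail-padded with their last value; padded samples
  carry masked targets and are excluded from the loss and from the
  returned labels.
* **Class imbalance.** `start` is roughly one sample in 200+; no class
  weighting is applied. A missed `start` at the head of a detected decay
  is recovered by the rule engine (promotion rule), so the pipeline does
  not depend on the network nailing the rare class.
* **Hyperparameter search.** `tune_segmenter()` is a seeded random
  search over the box with an 80/10/10 subject split, scored by
  validation misclassification — the contract is the objective and the
  split, not the optimizer brand, and the budget is an argument.

## The rule engine

`apply_rules()` turns raw labels into valid segments with five
corrections and four quality-control steps, applied in a fixed order
(R1: fill 1-2-sample `na` holes inside measurement runs; R2: promote the
first of an unheaded run of >= 10 `measurement` samples to `start`; R3:
discard the later of two starts within 30 samples; R4: exclude
measurements starting at <= 20 mmHg or never dropping below 20 mmHg;
R5: relabel `na` holes between a start and its following measurement
samples; QC1: recenter each start on the highest mitoPO2 among the start
and the next six samples; QC2: shift a start past a sharp rise in the
next three samples; QC3: drop segments with a > 50 mmHg first-step drop;
QC4: drop segments of <= 10 samples). Conventions the rule text leaves
open:

* **"Sharp rise"** (QC2) is operationalized as a rise of more than
  2 mmHg between consecutive samples: large enough that Gaussian noise
  of the magnitude seen on these devices (~1.5 mmHg) rarely triggers it,
  small enough to catch genuine release artifacts. QC2 iterates until
  the first three steps after the start contain no such rise.
* **Boundaries.** "Within 30 data points" discards the later start at
  spacing <= 30; "duration > 10 s" keeps segments of >= 11 samples;
  "begins below 20 mmHg" excludes a start at exactly 20. The QC1 window
  is the start plus the next six samples (7 samples), truncated at the
  segment end.
* **Segment association for R4.** When R4 runs, gaps that R5 will later
  fill may still sit inside a segment (e.g. the hole left by a discarded
  double start), so R4 spans a start's measurement runs across such
  `na` gaps when computing the minimum.
* **Idempotence.** A final sweep re-checks every surviving segment
  against all requirements simultaneously (including start spacing after
  QC shifts) and clears `measurement` labels that belong to no surviving
  segment. Cleaned labels are a fixed point: re-running the engine
  changes nothing and logs nothing.

Every change is logged once (rule id, affected 0-based indices, action),
so a reviewer can audit exactly which rule touched which samples.

## The synthetic cohort generator

Clinical sessions cannot be redistributed, so `generate_cohort()`
produces sessions with the statistical structure the pipeline assumes:
alternating baseline plateaus and stop-flow measurements, each
measurement an RK4 decay at 1 Hz followed by an exponential
reoxygenation toward the next baseline, with i.i.d. Gaussian noise on
top and exact ground truth (parameters, start index, analytic Vmax)
recorded per measurement.

Defaults, chosen once as plausible for cutaneous sessions in adults
after ALA application: baseline ~N(60, 10) mmHg truncated at 30;
noise sd 1.5 mmHg; per-measurement kinetics v0 ~ U(4, 14) mmHg/s,
p50 ~ U(1, 6) mmHg, z ~ U(0.02, 0.15)/s (per-subject mean Vmax lands in
the 6-9 mmHg/s range typical of published cohorts); recovery time
constant 10 s; baseline gaps U(40, 90) s so consecutive starts are
always more than 30 s apart; 8 measurements per subject.

One structural choice deserves emphasis: **compression is held for the
full 120-s recording** (`hold_at_floor = TRUE`), so the trace decays to
its consumption/influx floor and sits there until release, exactly as
the device records. An early-release variant (`hold_at_floor = FALSE`,
release once the trace crosses `stop_level`) is available; it produces
measurement durations of 10-15 s for fast decays — at the edge of the
"duration > 10 s" validity rule — which is useful for stress-testing the
rule engine but is not how the recordings are made.

What the generator does **not** emulate: PpIX photophysics and
delayed-fluorescence lifetimes, probe pressure mechanics, baseline
drift, movement artifacts, or autocorrelated noise. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's machinery is
correct under its stated assumptions, not that any specific clinical
accuracy carries over; clinical figures in the literature depend on
datasets this package cannot access, and nothing here claims to
reproduce them.

`adversarial_fixture()` complements the generator: a deterministic,
noise-free session containing exactly one instance of every pathology
the rule engine handles, with hand-computed expected output frozen in
the tests.

## Agreement statistics

`match_starts()` pairs detected and reference start points one-to-one,
greedily by ascending absolute offset (ties: earlier reference first),
within a ±5-sample tolerance, and reports accuracies at offsets 0, 1, 3
and 5. The reference count is the denominator; surplus detections are
reported separately, not penalized. An exhaustive-assignment oracle in
the tests confirms the greedy matching attains the optimal match count
on small cases.

`bland_altman()` reports bias, its 95% CI from the paired t
distribution, and limits of agreement `bias ± 1.96 sd`. For designs with
repeated measurements per subject and unequal replicate counts,
`extended_loa()` decomposes the variance of a single difference by
one-way ANOVA:

$$\hat\sigma_d^2 = \underbrace{\max\!\left(0, \frac{MSB - MSW}{n_0}\right)}_{\text{between subjects}} + \underbrace{MSW}_{\text{within}},
\qquad n_0 = \frac{N - \sum m_i^2 / N}{k - 1}$$

with limits `bias ± 1.96 σ_d`; the bias CI uses the variance of the
overall mean under the same components model with k-1 degrees of
freedom. Both degenerate cases collapse to the plain limits (all
single-replicate, with a warning; balanced with zero within-subject
variance). `comparability()` deems two methods comparable when the bias
CI lies inside a ±0.3 mmHg/s margin, read inclusively at the boundary.

## Problem sizes and runtimes

The test suite trains one network (20 synthetic subjects, ~3400
windows, tuned default hyperparameters, about 1.5 min on one CPU core)
and reuses it across the behavioural tests; detection quality is scored
on a disjoint 30-subject cohort, and repeatability on a further
20-subject cohort. Vmax recovery is assessed on 200 parameter draws
from the physiological box, each fitted noiseless and with 1.5-mmHg
noise. These sizes keep the full suite comfortably within a coffee
break while leaving every claim actually computed, not asserted.

## Known limitations

* The segmenter is trained on synthetic sessions; applying it to real
  device exports requires retraining (`train_segmenter()`) on labeled
  clinical traces, which the package supports but cannot ship.
* Oxygen delivery (mitoDO2) analysis and sigmoid-based alternative fits
  are out of scope.
* The rule engine implements fixed thresholds (20 mmHg, 30 samples,
  50 mmHg, 10 s); these are the published validity criteria, not tunable
  knobs, and the package deliberately does not expose them as options.
* Vendor export formats are not parsed; the package defines a plain
  two-column CSV dialect (see `read_trace()`) and leaves conversion to
  the user.
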