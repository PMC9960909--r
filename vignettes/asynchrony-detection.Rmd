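---
title: "Detecting patient-ventilator asynchrony from ventilator waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting patient-ventilator asynchrony from ventilator waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventasync)
```

## Scope and data model

`ventasync` analyses the three waveforms every ICU ventilator displays:
airway pressure `paw` (cmH2O), `flow` (L/min) and `volume` (mL), sampled at
50 Hz. A recording is a `vent_stream` — a tibble of synchronized samples
carrying the sample rate and metadata as attributes. The pipeline is

1. `clean_stream()` — repair or reject non-finite samples;
2. `segment_breaths()` — partition the recording into breaths;
3. `detect_double_trigger()` / `detect_ineffective_trigger()` — flag
   asynchrony events;
4. `compute_ai()` — the sliding-window asynchrony index and alarms;
5. `evaluate_run()` — score detections against gold annotations;
6. `generate_report()` — the per-window analysis report.

Everything downstream of `clean_stream()` is deterministic, and the
simulator is deterministic given a seed, so the full pipeline is a pure
function of configuration and seed.

## Breath segmentation

No published segmentation rule accompanies the detection rules this package
implements, so segmentation uses the standard clinical approach:
flow-threshold crossing with hysteresis. Inspiration starts where flow
crosses above `flow_trigger_threshold` (+2 L/min by default), having been
below it since the previous cycle; expiration starts at the first subsequent
crossing below `flow_cycle_threshold` (-2 L/min). Candidates with
inspiratory time under 0.1 s or total duration under 0.3 s are discarded as
noise. Indices are 1-based with half-open breath spans
`[trigger_index, end_index)`; `end_index` is the next trigger, or one past
the stream end for the final breath, so breath spans tile the recording.

Raising the trigger threshold can only remove breaths on clean signals, and
the package asserts that property on noise-free simulations. It is *not* a
theorem under noise: noise hovering above a low threshold can leave the
detector unarmed when true inspiration begins, so a lower threshold can
paradoxically miss real breaths. Threshold choice on noisy data is a
trade-off, not a monotone dial.

The "average inspiratory time" in the double-trigger rule is implemented as
a rolling mean over the last `ti_avg_window = 10` breaths
(`mean_inspiratory_time()`). A global mean would drift with mode changes;
ten breaths (~40 s) is long enough to be stable and short enough to adapt.
PEEP is estimated as mean `paw` over the final 0.2 s of expiration, a
stable end-expiratory plateau.

## Double-trigger detection

Each consecutive breath pair `(i, i+1)` is examined; the pair is one
double-trigger event, anchored at breath `i`'s cycle point, when either

* breath `i` has no effective expiration — `te_s == 0`, or its volume at
  breath end stays more than `volume_baseline_tol = 20` mL above the volume
  at its trigger ("the volume-time curve does not fall back to baseline"); or
* `te_s(i) < dt_te_ratio * mean(Ti)` with `dt_te_ratio = 0.5`, strictly.

The two clauses are disjunctive, comparisons are strict, and one qualifying
pair yields exactly one event: the pair of machine cycles is a single
asynchrony occurrence. The 20 mL baseline tolerance operationalises
"returns to baseline" at a level well above integration noise but far below
any clinically meaningful retained volume.

## Ineffective-trigger detection

An ineffective effort appears as a *flow deflection*: expiratory flow
transiently rises then falls. Within each expiratory segment the detector

1. smooths flow with a `derivative_smoothing_window = 5` sample moving
   average (raw 50 Hz first differences are noise-dominated);
2. takes the first difference of the smoothed flow;
3. locates local extrema via sign changes of that derivative, carrying the
   last nonzero sign across flat runs;
4. refines each extremum position to the raw curve's extremum within half a
   smoothing window — so measured features are not biased by the averaging;
5. forms candidate deflections `(m1, p, m2)`: a local maximum `p` bracketed
   by local minima;
6. measures `amplitude = flow(p) - max(flow(m1), flow(m2))` (raw flow,
   referenced to the *higher* bracketing minimum — the conservative choice
   when the deflection interrupts a rising decay curve) and
   `duration = t(m2) - t(m1)` (min-to-min; `it_duration_mode = "max_to_min"`
   selects the peak-to-minimum convention instead);
7. emits an event anchored at `p` when `amplitude > 5` L/min **and**
   `duration > 0.12` s, both strict.

Because amplitude is a difference of flow values, detection is invariant to
constant flow offsets. Raising either threshold can only remove events — a
property the test suite sweeps explicitly.

## Asynchrony index and alarms

For each window `[t - window_s, t)` advancing in `step_s = 1` s steps:

```
AI = 100 * n_events / (n_cycles + n_ineffective)
```

The denominator counts breaths by trigger-time membership (unambiguous for
boundary-straddling breaths) plus ineffective-trigger events — failed
efforts are breaths the cycle count misses. Double triggers are machine
cycles already counted, so they add to the numerator only. Windows are
half-open on the right, so with `step_s == window_s` event counts across
windows sum exactly to the total. The default window is 240 s, the midpoint
of the conventional 3–6 minute band (enforced by `ai_config()` unless
`strict = FALSE`); a zero-denominator window reports `NaN` with the alarm
off, since an index over no cycles is meaningless. The alarm fires at
`AI >= severe_threshold_pct` (10%), and `alarm_episodes()` merges
consecutive alarmed windows into episodes.

## The simulator

`simulate_ventilation()` produces labelled volume-control recordings from a
single-compartment model: constant inspiratory flow delivers
`tidal_volume_ml` over `ti_s`; airway pressure during insufflation follows
the equation of motion `Paw = R*Q + V/C + PEEP`; expiration is passive
exponential decay with time constant `tau = R*C`, integrated by forward
Euler at the native 50 Hz step (`mechanics_step()` is one such step). At the
defaults — R = 10 cmH2O/(L/s), C = 50 mL/cmH2O, so `tau` = 0.5 s — Euler at
20 ms deviates from the closed form by under 1% of the peak expiratory flow,
which the physics tests bound at 2%. Defaults emulate an adult
volume-control patient: VT 440 mL, PEEP 5 cmH2O, 15 breaths/min with 1 s
inspiration. The volume channel integrates machine flow and resets at each
trigger, as ventilator displays do.

**Double-trigger injection** truncates a flagged breath's expiration at a
uniform draw from `(0, 0.4 * ti_s)` and inserts a second full insufflation
inside the same breath period, guaranteeing `Te < 0.5 * mean(Ti)` while
keeping the breath schedule exact. The configuration is rejected when the
period cannot hold `2.4 * ti_s` plus three expiratory time constants —
otherwise the second breath's own shortened expiration would leak into the
volume-baseline rule.

**Ineffective-trigger injection** carves a smooth deflection into the decay
curve: flow dips `it_undershoot_lpm` (2 L/min) below the curve, climbs to a
peak held just below zero flow, falls to a shallow right minimum, and
rejoins the decay, with a concurrent 1.5 cmH2O pressure dip. By construction
the min-to-min span equals `it_duration_s` and the amplitude against the
higher (right) minimum equals `it_amplitude_lpm` — precisely the features
the detector measures. Two constraints force this shape rather than a
simple additive bump: late in expiration the base curve is nearly flat, so
an 8 L/min bump would cross the +2 L/min trigger threshold and falsely
trigger segmentation (a genuinely *ineffective* effort must not); early in
expiration the decay slope exceeds 30 L/min/s, which would swallow any
small additive undershoot, leaving no left bracketing minimum for the
detector's `(min, max, min)` morphology. Anchoring the deflection to the
curve satisfies both, and matches the clinical picture of an effort
interrupting the early decay. The carved edges are at least five samples
wide so the bracketing minima survive the detector's default smoothing; the
effort is assumed to move no net volume, so the volume channel follows
passive mechanics.

Random draws are consumed in fixed order (per slot: DT decision, then
truncation or IT decision), so identical configurations and seeds give
bit-identical output; flow noise, when enabled, is drawn last.

## What the simulator does and does not establish

Simulated waveforms are noise-free by default, perfectly periodic, and
contain events whose morphology matches the detectors' feature definitions
by construction. Perfect sensitivity and specificity on such data show that
the implementation is faithful to the stated rules and that the pipeline's
bookkeeping (indices, labels, margins) is exact — they say nothing about
performance on patient data, where reported sensitivities for rules of this
family are far below 100%. Real signals add secretions and cardiogenic
oscillations, mode changes, leaks, and efforts of every amplitude straddling
the thresholds; none of these are modelled. Pressure-support realism
(patient-driven pressurisation), multi-compartment mechanics and leak
modelling are explicitly out of scope.

## Evaluation conventions

Events are projected onto breaths (`label_breaths()`): a breath is positive
for a type iff at least one event of that type is anchored inside its span,
so several detections within one breath count once. Events outside every
breath are attached to the nearest breath within 0.5 s (annotation
timestamps often sit on boundaries), otherwise dropped with a warning.
Metrics are reported on the percent scale rounded **half-up** to 2 decimals
(`round_half_up()`), the convention of the published tables this package
reproduces (481/716 = 67.179...% prints as 67.18); banker's rounding would
differ on exact ties. Undefined ratios (zero denominators) are `NaN`, never
silently 0 or 100.

## Numerical choices and degenerate inputs

* Sample-rate inference from a `time` column accepts up to 5% inter-sample
  jitter (real exports have clock jitter); beyond that the file is rejected.
* Interpolating more than 10% invalid samples per channel is refused — the
  detection thresholds are meaningless on such a signal — but a single
  invalid sample is always repairable so minimal streams can be cleaned.
* A stream opening mid-insufflation yields a breath at sample 1: the
  pre-stream state is taken as below threshold.
* Flat flow runs contribute no extrema (the last nonzero derivative sign is
  carried forward), so plateaus cannot spawn spurious deflections.
* A window longer than the recording produces a single truncated window
  with a warning rather than an error.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use recordings of 40–900 s
(10–240 breaths) at 50 Hz, sizes at which every property being asserted —
count equality, feature fidelity, margin conservation, determinism — is
already fully exercised; the published-table computations are exact at any
size.
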