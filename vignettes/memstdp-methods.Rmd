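---
title: "Methods: simulating binary memristive STDP networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating binary memristive STDP networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstdp)
```

This vignette documents the model behind `memstdp`: what is simulated,
which choices were genuinely open and how they were resolved, and what
the simulated experiments do and do not establish.

## The device model

Each synapse is a one-transistor/one-resistor (1T1R) element: an HfO2
RRAM resistor in series with a gating transistor. The behavioral model
keeps exactly one state variable, the resistance `R`, and two target
levels:

| parameter | default | meaning |
|---|---|---|
| `r_lrs_target` | 10 kΩ | low-resistance state reached on set; fixed by the transistor compliance current, i.e. by the gate amplitude |
| `r_hrs_target` | 1 MΩ | high-resistance state reached on reset; fixed by the top-electrode amplitude |
| `v_set_threshold` | +1.0 V | gated set transition at or above this voltage |
| `v_reset_threshold` | −1.5 V | gated reset transition at or below this voltage |
| `sigma_lrs`, `sigma_hrs` | 0 | log-normal spread of each freshly sampled level |

Switching is instantaneous and complete: any sufficient pulse overlap
produces a full transition to a freshly sampled level, never a partial
state. This matches the abrupt set/reset characteristics of the devices
being modeled, where the resistance after a single plasticity event is
either the LRS or the HRS level. The absolute resistance values are
declared defaults, not measurements — the experiments only depend on the
LRS/HRS conductance ratio being large (100× here), which keeps the five
recognition levels well separated. Both levels are configurable.

The gray-scale encoding maps a graded gate amplitude to a graded LRS
level through the compliance current. The mapping is conductance-linear,
`1/R = (v_g / v_g_full) / r_lrs_target`, clipped below at the HRS
conductance. This is the simplest monotone choice consistent with a
compliance current that scales with gate overdrive; the true device
relation is not specified by the characterization the model is built on,
so only monotonicity and the full-scale identity should be relied upon.

## Pulse-overlap STDP

A PRE spike opens the transistor gate for `t_gate` = 10 ms. A POST fire
drives the top electrode with a positive pulse (onset at the fire time)
followed by a negative pulse `delay_neg` = 10 ms later, each
`t_fb_pulse` = 1 ms wide; between pulses the electrode sits at a −0.2 V
read bias. The plasticity of one PRE/POST pairing with delay
`Δt = t_POST − t_PRE` follows from rectangular-pulse overlap:

* overlap of the open gate with the positive pulse → set (potentiation);
* overlap with the delayed negative pulse → reset (depression);
* both overlaps (possible in a narrow band of slightly negative delays)
  → the pulses act in chronological order and the later reset wins;
* `|Δt| ≥ t_gate` → identity, by contract. A literal rectangular-pulse
  model would extend depression to `Δt ∈ [−t_gate − t_fb_pulse,
  −t_gate]`; the device characterization reports no change beyond the
  gate width, so the window is truncated there. The engine never
  generates delays in the truncated band, and the equivalence tests
  against the dense-time oracle are unaffected.

An overlap guard `eps_overlap` (0.01 ms) absorbs floating-point edge
cases. `delay_neg` defaults to `t_gate` so the negative pulse cannot
reach back into the gate window that caused the fire, but does overlap a
gate opened in the following epoch — this is the placement that makes
pattern presentations potentiate and subsequent noise frames depress.

The `stdp_curve()` surface is evaluated with variability disabled; its
sign structure (potentiation only from above the LRS, depression only
from below the HRS, confined to `|Δt| < t_gate`) is the state-dependent,
multiplicative plasticity the experiments rely on.

A 100× accelerated preset (`timing_preset("accelerated")`: 100 µs gate,
10 µs feedback pulses, +3.3 V positive feedback to enable set at the
shorter timescale) is a parameter set, not separate code.

## Neuron and event engine

Internal potentials are kept in **LRS units**: one epoch of one active
full-LRS synapse contributes exactly 1. The hardware the model mirrors
reports thresholds in volts through an unspecified transimpedance gain,
so voltages are not unit-convertible; what is well defined is the
calibration rule — the training threshold fires on 2 simultaneous
full-LRS PRE spikes — which fixes it at 2.0 LRS units. A cosmetic
`volts_per_unit` constant (0.36 V/unit, so the threshold displays as
0.72 V) affects reporting only.

The engine quantizes time into epochs of `t_epoch` = `t_gate`. Within an
epoch the order of operations is:

1. apply the optional per-epoch potential decay (default: none — the
   neuron integrates digitally until fire or explicit discharge; a
   threshold of 2 units with per-epoch increments of order 0.04 from an
   HRS array is only reachable because potentials accumulate across
   epochs);
2. integrate the gated synaptic current into every POST with the
   pre-update resistances — the gate is open for the whole window while
   feedback pulses only act at its end;
3. evaluate fires at epoch end (fire-at-threshold, `≥`), in a randomized
   order when there are several POSTs; a firing POST potentiates its
   open gates, discharges, schedules its negative pulse, and immediately
   inhibits the others (a POST pushed below threshold in the same epoch
   does not fire);
4. land pending negative pulses from the previous epoch's fires on this
   epoch's open gates — except for POSTs that fired again this epoch,
   whose fresh feedback spike *replaces* the pending pulse (the feedback
   driver holds at most one).

Point 2 and the replacement rule in point 4 deserve emphasis: if the
pending depression were applied before integration, a pattern epoch
following a pattern fire would first reset the just-learned synapses and
then fail to fire, and stable learning would be impossible. Integrating
first and letting a new fire replace the pending pulse is what the
waveform timing actually implies (the pending negative pulse and the new
fire's positive pulse coincide at the end of the gate window), and it is
what makes "selective potentiation of pattern synapses, unselective
depression elsewhere" work.

The `dense_time_oracle()` is an independent check of all of this: it
lays every gate and feedback pulse out on a 0.1 ms grid, measures
overlaps explicitly, and applies the switching rules in chronological
order. The test-suite verifies that the epoch engine and the oracle
produce identical final weight grids on randomized 50-epoch schedules
(20 seeds, 1- and 2-POST networks).

## Stimuli

Binary images on 4×4 (16 PREs) or 3×3 (9 PREs) grids, flattened
row-major with a top-left origin. The library ships the 4-pixel diagonal
(`diag4`) used for static learning; the second and third training images
of the dynamic-learning experiment are defined only graphically in the
source experiments, so the library ships stand-ins (`antidiag4`,
`corners4`) — any 4-pixel image reproduces the protocol's logic, though
*how fast* a new image overwrites an old one depends on their overlap
(below). Noise frames are per-pixel Bernoulli at density 3% ("3% of
pixels on average" could also mean a fixed per-frame count; the
independent-pixel reading is declared). Pattern and noise are mutually
exclusive within an epoch, drawn with pattern probability 0.5.

The 3×3 perimeter shift advances active border pixels along the cycle
(0,0) → (0,1) → (0,2) → (1,2) → (2,2) → (2,1) → (2,0) → (1,0) (0-based
(row, col); counter-clockwise with the y axis pointing down); the center
pixel is immobile and eight steps are the identity.

## The experiments, and what passing them shows

**Static learning** (`run_training`): from an all-HRS array under the
default stochastic schedule, the diagonal pattern is fully learned
(every pattern synapse within 2× of the LRS target, every background
synapse above half the HRS target — the declared, configurable adherence
criterion) in a median of ~90 epochs, well within the 300-epoch budget,
in essentially all seeded runs.

**Steady-state flicker.** After learning, the weight grid is not frozen:
a noise frame presented right after a fire occasionally depresses a
pattern synapse (re-potentiated at the next pattern fire), and
accumulated noise current occasionally fires on a noise epoch, setting a
transient background synapse whose expected lifetime is long (~130
epochs: clearing requires another noise hit right after a fire). The
*instantaneous* probability of strict full-grid adherence in the
stationary regime is therefore only ~0.75 at 3% noise, even though the
pattern itself is stably retained — the weight-trace logs show exactly
this background toggling. Any check that reads a single epoch's snapshot
inherits this flicker; checks of *reaching* adherence are robust.

**Dynamic learning**: when the presented image changes, the new image's
synapses are potentiated within a few tens of epochs, but synapses of
the old image persist until a noise frame hits them right after a fire
(~0.0075/epoch each, and noise-epoch fires can re-set them). With fully
disjoint old/new images (4 stale pixels, as with `diag4` → `antidiag4`)
full adherence within a 300-epoch phase is the exception rather than the
rule; with the 400-epoch third phase and partially overlapping images it
is reached in most runs. The overwrite direction itself — old-only
pixels end HRS, new-only pixels end LRS — is robust.

**Recognition** (`run_recognition`): with STDP disabled, each of the
1820 four-of-sixteen test patterns is integrated for one epoch and the
potential discharged. On ideally learned weights the potential is
exactly `k + (4 − k) · 0.01` LRS units for overlap `k`, five distinct
levels; the recognition threshold is placed midway between the top two
(3.5 units — the printed recognition voltage is not unit-convertible, so
the midpoint rule is the declared choice), and only the training pattern
fires.

**Two-neuron tracking** (`run_tracking`): two POSTs with 40%
multiplicative winner-take-all inhibition learn two disjoint 3-pixel
bars, then track them around the border. The initial weights default to
all-LRS: from an all-HRS preparation the two POSTs are exactly
symmetric, the first to specialize then fires every few epochs, and its
inhibition caps the loser's potential far below threshold forever (a
neuron with no low-resistance synapse has no way to accumulate fast
enough between inhibition events) — the second neuron can never
specialize. An all-LRS start keeps both neurons fire-capable; the
competition is then resolved by the pending-pulse mechanism (the
tie-break loser's freshly potentiated synapses are depressed the next
time the shared image repeats and it loses again). Each shift moves a
3-pixel bar by one border cell, so a locked POST needs exactly one set
and one reset — two switched synapses per POST per phase, which is the
modal outcome across seeds; the winner-take-all exclusivity (the two
POSTs never adhere to the same image) holds in every tested seed.

## Numerical and bookkeeping choices

* Fire evaluation once per epoch, at epoch end, crossing with `≥`.
* Simultaneous-fire tie-breaks drawn from the run's seeded stream;
  at most one pending negative pulse per POST.
* All randomness flows through R's global RNG: a single `set.seed()`
  (or the `seed` arguments) reproduces schedules, device sampling, and
  tie-breaks bit-exactly; logs carry the seed and a config hash.
* Degenerate inputs are contract errors (non-positive pulse widths,
  shape mismatches, overlapping tracking patterns, unknown config keys),
  not silent coercions.

## Problem sizes

The shipped experiments are desk-scale by design: 16 or 18 synapses,
schedules of 300–5000 epochs, 20-seed replications. The full test-suite
runs in well under a minute of simulation time; the acceptance sweep
(~120 seeded runs of up to 5000 epochs) in tens of seconds.

## Known limitations

* No electrothermal filament physics, forming, retention, endurance, or
  I–V tracing: the device is two thresholds and two (optionally noisy)
  levels.
* No analog circuit simulation (transimpedance stage, ADC), axonal
  delays, or refractory periods; spikes are rectangular pulses.
* The absolute LRS/HRS values, the gray-level mapping shape, and the
  stand-in patterns for the second and third training images are
  declared choices, not fitted to device data.
* Synthetic noise frames are independent Bernoulli pixels; real sensor
  noise with spatial or temporal correlation may change the stability
  window.
* The epoch engine assumes `t_epoch = t_gate` and `delay_neg = t_gate`
  for its feedback bookkeeping; other geometries are validated only
  through the dense-time oracle.
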