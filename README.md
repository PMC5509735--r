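# memstdp

Behavioral simulation of spiking perceptron networks whose synapses are
binary memristive (1T1R RRAM) devices updated by pulse-overlap
spike-timing-dependent plasticity (STDP).

The package is aimed at neuromorphic-hardware researchers who want a
desk-scale, reproducible model of unsupervised Hebbian learning with
resistive-switching synapses: a retina layer of PREs drives one or two
leaky integrate-and-fire POSTs through one-transistor/one-resistor HfO2
RRAM synapses whose only weight levels are a low-resistance state (LRS)
and a high-resistance state (HRS). It reproduces, in simulation, static
and dynamic pattern learning under stochastic stimulation, exhaustive
pattern recognition with no false positives, and two-neuron
winner-take-all tracking of a moving image.

## The model

**Synapse.** Each synapse is a resistor `R` behind a transistor gate. A
positive top-electrode pulse at or above the set threshold (default
+1.0 V) switches a gated device to the LRS (default 10 kΩ); a negative
pulse at or below the reset threshold (default −1.5 V) switches it to the
HRS (default 1 MΩ). Switching is abrupt and complete — the weight
`w = 1/R` is binary — with optional log-normal level variability.

**Plasticity.** A PRE spike opens the gate for `t_gate` = 10 ms. A POST
fire emits a feedback spike: a +2 V pulse at the fire time and a −1.6 V
pulse `delay_neg` = 10 ms later, each 1 ms wide. The conductance-change
ratio across one pairing is

    eta = R_before / R_after,

with potentiation (`eta > 1`, set) when the gate overlaps the positive
pulse (0 < Δt < 10 ms, Δt = t_POST − t_PRE), depression (`eta < 1`,
reset) when it overlaps the delayed negative pulse (−10 ms < Δt < 0), and
no change outside the window — multiplicative, state-dependent STDP.

**Neuron.** Per 10 ms epoch the POST integrates the current of gated
synapses,

    I_post = V_TE * sum_n 1/R_n        (active synapses only),

kept in "LRS units" (one full-LRS active synapse per epoch = 1 unit). The
training threshold is calibrated so that 2 simultaneous full-LRS PRE
spikes trigger a fire (2.0 units). In 2-POST networks a fire reduces the
other neuron's potential by 40% (winner-take-all lateral inhibition).

**Protocol.** Training presents, per epoch, the target image or a sparse
noise frame (3% pixel density) with equal probability. Fires on pattern
epochs potentiate pattern synapses; the delayed negative pulse lands on
whatever is presented next, so noise frames right after a fire depress
background synapses. Recognition disables STDP and sweeps all
`choose(16, 4) = 1820` four-pixel test images.

## Worked example

```r
library(memstdp)
set.seed(42)
pat <- builtin_pattern("diag4")                      # 4-pixel diagonal
sch <- build_schedule(list(training_phase(pat, 300)))
log <- run_training(network_config(), "hrs", sch)    # all-HRS start
summary(log)
#> training summary (1 POST)
#>  phase epochs fires n_set n_reset adherent changed_synapses
#>      1    300   109     8       4   image1                4
first_adherence_epoch(log, pat)
#> [1] 92
```

The network starts with all 16 synapses in the HRS, fires 109 times in
300 epochs, and from epoch 92 onward the 4 diagonal synapses are in the
LRS with the 12 background synapses in the HRS — the pattern is learned.
Sweeping all 1820 four-pixel test patterns over the trained weights:

```r
summary(run_recognition(log$net, pat, threshold = 3.5))
#> recognition sweep: 1820 patterns, threshold 3.5 LRS units
#>   distinct potential levels: 5; fires: 1
#>   overlap n_patterns v_min v_max n_fired
#> 1       0        495  0.04  0.04       0
#> 2       1        880  1.03  1.03       0
#> 3       2        396  2.02  2.02       0
#> 4       3         48  3.01  3.01       0
#> 5       4          1  4.00  4.00       1
```

The internal potential collapses onto five levels, one per count of
pixels shared with the training pattern, and with the recognition
threshold between the overlap-3 and overlap-4 levels only the training
pattern itself fires — no false positives.

A command-line front end wrapping the same functions (subcommands
`train`, `recognize`, `track`, `stdp-curve`) ships in
`inst/cli/memstdp.R`, with example configurations under `inst/extdata/`.

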