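Package: memstdp
Title: Simulation of Spiking Perceptron Networks with Binary Memristive
    Synapses and Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Behavioral simulator of perceptron-like spiking neural networks
    whose synapses are one-transistor/one-resistor (1T1R) resistive-switching
    memory (RRAM) devices with binary weights, updated by pulse-overlap
    spike-timing-dependent plasticity (STDP). Provides a threshold-switching
    device model with optional log-normal state variability, leaky
    integrate-and-fire post-neurons with winner-take-all lateral inhibition,
    an epoch-quantized event engine together with a dense-time waveform
    oracle for verification, stimulus generators (binary patterns, random
    noise frames, gray-scale encodings, perimeter-shifted variants), and
    reproducible protocols for stochastic unsupervised pattern learning,
    exhaustive recognition sweeps, and two-neuron dynamic pattern tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
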