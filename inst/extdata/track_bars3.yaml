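# Two-neuron winner-take-all tracking on a 3x3 retina: top and bottom
# bars, four counter-clockwise perimeter shifts, 1000 epochs per phase.
seed: 42
network:
  n_pre: 9
  n_post: 2
protocol:
  patterns: [top_bar3, bottom_bar3]
  n_shift_steps: 4
  epochs_per_phase: 1000
output: out
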