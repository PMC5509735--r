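# Static learning of the 4-pixel diagonal on a 4x4 retina: the default
# biological-timescale protocol (10 ms epochs, 50% pattern probability,
# 3% noise, threshold of 2 LRS units).
seed: 42
protocol:
  pattern: diag4
  n_epochs: 300
output: out
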