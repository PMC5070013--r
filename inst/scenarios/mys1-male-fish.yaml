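name: mys1-male-fish
type: fish_volume
description: >
  mys-1(n4075) mutant males; X territory recondensed to 9.87% of nuclear
  volume (n = 20), near the DNA-content prediction for the single X.
seed: 1
params:
  occupancy: 0.0987
  n_nuclei: 20
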