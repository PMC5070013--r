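name: wt-male-fish
type: fish_volume
description: >
  Wild-type male intestinal nuclei, X-paint FISH; decondensed single X
  occupying 15.74% of nuclear volume (n = 27).
seed: 1
params:
  occupancy: 0.1574
  n_nuclei: 27
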