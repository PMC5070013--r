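name: mys1-herm-fish
type: fish_volume
description: >
  mys-1(RNAi) hermaphrodites; X decompacted to 17.11% of nuclear volume
  (n = 36), near the 18% DNA-content prediction.
seed: 1
params:
  occupancy: 0.1711
  n_nuclei: 36
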