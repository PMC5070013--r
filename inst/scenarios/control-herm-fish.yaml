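name: control-herm-fish
type: fish_volume
description: >
  Control (vector RNAi) hermaphrodites; DCC-compacted X territories at
  9.41% of nuclear volume (n = 40).
seed: 1
params:
  occupancy: 0.0941
  n_nuclei: 40
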