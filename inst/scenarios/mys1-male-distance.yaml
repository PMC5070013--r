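name: mys1-male-distance
type: probe_distance
description: >
  mys-1(RNAi) males; compacted X brings the same probe pair to a median
  3D separation of 0.67 um (n = 16 nuclei).
seed: 1
params:
  separation_um: 0.67
  n_nuclei: 16
  spots_per_probe: 2
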