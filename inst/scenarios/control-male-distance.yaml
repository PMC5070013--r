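name: control-male-distance
type: probe_distance
description: >
  Control males, two X probes 1.2 Mb apart in tetraploid hyp7 nuclei;
  median 3D separation 1.06 um (n = 20 nuclei, 2 homolog pairs each).
seed: 1
params:
  separation_um: 1.06
  n_nuclei: 20
  spots_per_probe: 2
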