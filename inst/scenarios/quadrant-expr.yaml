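name: quadrant-expr
type: expression_quadrant
description: >
  Joint dpy-21-derepression / mys-1-repression response: 24% of X genes
  planted in the concordant (up in contrast A, down in contrast B)
  quadrant, 2-12% in the others; recovered with +/-0.1 log2 thresholds.
karyotype: XX
seed: 1
params:
  quadrant_probs:
    up_up: 0.02
    up_down: 0.24
    down_up: 0.07
    down_down: 0.12
  magnitude: [0.4, 1.2]
  null_sd: 0.02
  genes_per_mb: 200
  n_replicates: 3
  library_size: 6.0e7
  dispersion: 0.005
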