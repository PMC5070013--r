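name: xx-wt-expr
type: expression_xa
description: >
  Wild-type XX L3 expression; X-linked baseline medians scaled so the
  median X:A RPKM ratio of expressed genes is 0.88.
karyotype: XX
seed: 1
params:
  x_ratio: 0.88
  genes_per_mb: 200
  n_replicates: 3
  library_size: 3.0e7
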