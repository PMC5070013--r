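name: mys1-expr
type: expression_contrast
description: >
  mys-1(RNAi) XO hermaphrodites vs control XO: mild X-specific
  repression, planted X median log2 ratio -0.021 vs -0.008 on
  autosomes; deep low-dispersion libraries keep the X-median standard
  error below 0.01; one-sided rank-sum direction less.
karyotype: XO
seed: 1
params:
  x_log2_median: -0.021
  x_log2_sd: 0.05
  autosome_log2_median: -0.008
  autosome_log2_sd: 0.05
  direction: less
  genes_per_mb: 200
  n_replicates: 3
  library_size: 6.0e7
  dispersion: 0.02
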