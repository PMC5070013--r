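name: dpy21-expr
type: expression_contrast
description: >
  dpy-21(e428) XX mutants vs wild type: X-specific derepression with a
  planted X median log2 ratio of +0.447 against -0.080 on autosomes;
  one-sided rank-sum direction greater.
karyotype: XX
seed: 1
params:
  x_log2_median: 0.447
  x_log2_sd: 0.25
  autosome_log2_median: -0.080
  autosome_log2_sd: 0.10
  direction: greater
  genes_per_mb: 200
  n_replicates: 3
  library_size: 3.0e7
  dispersion: 0.05
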