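name: him8-viability
type: viability_chisq
description: >
  Progeny survival of him-8 hermaphrodites on mys-1 RNAi (54%, n = 1071)
  vs control vector (98%, n = 2090), compared by Pearson chi-square.
seed: 1
params:
  rate_a: 0.98
  n_a: 2090
  rate_b: 0.54
  n_b: 1071
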