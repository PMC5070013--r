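name: xx-chip-ratio
type: chip_ratio
description: >
  XX hermaphrodite H4K16ac ChIP; X per-copy acetylation density solved
  so the expected X read-fraction / copy-weighted genome-fraction ratio
  is 0.33 (DCC-depleted X), 1e6 reads.
karyotype: XX
seed: 1
params:
  total_reads: 1000000
  target_x_ratio: 0.33
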