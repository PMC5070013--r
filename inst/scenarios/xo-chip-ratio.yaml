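name: xo-chip-ratio
type: chip_ratio
description: >
  XO hermaphrodite H4K16ac ChIP; uniform per-copy density (acetylation
  parity), expected X ratio 1.0 against the reported 1.01; 1e6 reads.
karyotype: XO
seed: 1
params:
  total_reads: 1000000
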