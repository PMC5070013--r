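name: xx-chip-peaks
type: chip_peaks
description: >
  XX H4K16ac peak-density scenario: enrichment islands planted at
  52/Mb on X and 95/Mb on autosomes over a 0.33-depleted X background;
  recovered through binning, ploidy-aware normalization, z-scoring and
  broad-peak calling.
karyotype: XX
seed: 1
params:
  total_reads: 20000000
  target_x_ratio: 0.33
  islands_per_mb_x: 52
  islands_per_mb_autosome: 95
  island_fold: 12
  island_width_bp: [400, 1200]
  bin_size: 50
  z_min: 2.5
  merge_gap: 500
  min_len: 200
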