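---
title: "Models and methods behind xdosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xdosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`xdosage` implements the three quantitative assays used to dissect X
chromosome dosage compensation in *C. elegans* — chromosome-territory
FISH, H4K16ac ChIP-seq, and mRNA-seq expression skew — together with a
synthetic-data module that generates every input the analyses consume.
Because the analyses are calibrated against planted truth rather than a
downloaded data set, every stage is testable end to end by parameter
recovery: the packaged scenarios in `inst/scenarios` plant the effect
sizes the assays are expected to detect and `run_scenario()` recovers
them. This vignette explains the models, the defaults and why they were
chosen, the numerical choices, and what the synthetic data do and do not
emulate.

# FISH territory volumes

## Model

An intestinal nucleus is imaged as a multi-channel anisotropic voxel
grid: a DNA counterstain (DAPI-like) channel and a chromosome-paint
channel. The measurement is

> percent nuclear volume = 100 x |territory mask ∩ nucleus mask| /
> |nucleus mask|

with the nucleus mask taken from the DNA channel and the territory mask
from the paint channel. Territory voxels outside the nucleus mask are
clipped, so the statistic can never exceed 100%. Group summaries are the
per-group mean, sample standard deviation and n, and groups are compared
with the classical equal-variance two-sample Student's t-test (the
package deliberately implements the pooled-variance variant, not Welch's
test).

## Thresholding

The original measurement protocol specifies only that an intensity
threshold separates signal from background. We default to per-nucleus
Otsu thresholding (256-bin histogram, between-class variance maximized),
with the paint threshold estimated *within* the DNA mask; fixed and
fraction-of-maximum thresholds are available. Otsu was chosen because it
is parameter-free and reproducible; per-nucleus (rather than per-image)
estimation makes the measurement robust to nucleus-to-nucleus staining
differences. Note that on a strongly bimodal histogram the between-class
criterion is nearly flat across the empty gap between modes, so two
correct implementations can return different thresholds inside the gap;
any of them separates the classes, which is what the volume statistic
needs.

## Synthetic nuclei

`gen_nucleus_stack()` plants an ellipsoidal nucleus (default semi-axes
16 x 16 x 12 voxels at 0.2 x 0.2 x 0.3 um) and a connected territory
constructed as the ellipsoid cap cut by a randomly oriented plane whose
voxel count matches the requested occupancy. A cap was chosen because a
chromosome territory is a connected, roughly convex sub-volume; the
realized (discretized) occupancy of every nucleus is recorded in the
truth table. Intensities are two-level (background 10, signal 100)
plus Gaussian noise (sd 8 by default); the imaging noise level is not
reported for the original experiments, so it is a package choice exposed
in the parameters. Between-nucleus biological variability is modelled as
a Gaussian jitter of the true occupancy with sd 1.2 percentage points;
this value was fixed a priori so that the group-mean recovery tolerance
of +/-0.6 percentage points corresponds to at least two standard errors
at the smallest packaged group size (n = 20). The synthetic images have
sharp object boundaries and no point-spread function, chromatic shift or
depth attenuation, so passing recovery tests demonstrates the
correctness of the measurement chain, not robustness to real optics.

# Probe-pair 3D distances

Two probe channels carry Gaussian spots (sd 0.12 um) at a planted
physical separation; hypodermal hyp7 nuclei are tetraploid, so the
packaged scenarios plant two homologous pairs per nucleus. Spots are
detected as 26-connected components above a fraction-of-maximum
threshold (components under 2 voxels are discarded as noise), localized
by intensity-weighted centroids, converted to micrometres with
anisotropic voxel scaling (voxel-centre convention), and paired across
channels by greedy globally-closest matching: repeatedly take the
closest (A, B) pair and remove both. Homolog pair centres are kept at
least 2 um apart by the generator, which makes the greedy assignment
unambiguous; for adversarially placed spots greedy matching is not
guaranteed to equal the minimum-weight matching, a known property of the
greedy rule (the tests assert equality in the well-separated regime and
the general guarantee that the greedy total is never below the optimal
total). Per-pair separations are jittered with sd 0.10 um around the
planted value, a spread fixed a priori so the median over the packaged
group sizes recovers the planted separation within the stated
+/-0.05 um.

# Ploidy-aware ChIP-seq processing

## Normalization

Reads are binned by midpoint (default 50 bp bins). Coverage is
normalized to the genome-wide median bin coverage excluding the
mitochondrial chromosome. In XO samples the single-copy X receives half
the per-cell sequencing depth of the autosomes, so X bins are divided by
*half* the autosomal median while autosomal bins are divided by the
median itself, putting both on a per-copy scale. The same rule is
applied to the input track, and the final enrichment score is the
bin-wise difference (normalized ChIP minus normalized input). The order
of operations — normalize each track, then subtract — is recorded in the
output provenance.

## Read-fraction ratio

The chromosome-level summary is the fraction of (non-mitochondrial)
reads on a chromosome divided by its copy-weighted genome fraction
(length x copy number over the copy-weighted total). Copy weighting is
what makes an XO sample with equal per-copy acetylation give an X ratio
of 1.0: the single X holds ~10% of the male genome and receives ~10% of
the reads. Without copy weighting the XO parity ratio would be ~0.5,
inconsistent with the reported near-1 value, which is why the
copy-weighted definition was adopted.

## Z-scoring and broad peaks

Enrichment scores are standardized against a background estimate. The
default background is median/MAD over all non-mitochondrial bins, which
is robust to the minority of enriched bins and invariant to constant
offsets; an alternative treats nonpositive enrichment values as the
lower half of a symmetric background centred at zero. The broad-peak
caller takes maximal runs of bins with z at or above `z_min` (default
2.5), merges runs separated by less than `merge_gap` (500 bp), and drops
merged peaks shorter than `min_len` (200 bp). All three are exposed.
One caveat worth knowing: for a merge-then-filter caller the peak count
is not strictly monotone in `z_min` on arbitrary signals (raising the
threshold can split one merged peak into two); it is monotone for the
plateau-like islands the caller is designed for, and that is the regime
the property tests cover.

## Synthetic reads

`gen_chip_reads()` draws read positions per chromosome with expectation
proportional to copy number x length x per-copy density, decomposed as a
uniform background plus an excess component on planted enrichment
islands (density multiplied by the island fold). Input reads follow copy
number x length only. Islands are placed one per equal-width slot with
jitter, guaranteeing edge separations larger than the merge gap so the
planted count is identifiable. The packaged XX peak scenario plants
islands at 52/Mb on the X and 95/Mb on the autosomes over an X
background depleted to the reported read-fraction ratio of 0.33 (the X
per-copy density factor is solved analytically from the karyotype).
Island fold 12 and 2e7 reads were fixed a priori so that X island bins
clear the z = 2.5 threshold by a comfortable margin despite the
depleted X background (expected island z around 5-6 at 50 bp bins); at
substantially lower depth or fold the recovery of the planted density
degrades for the X specifically, which is a property of the planted
depletion, not of the caller.

## Genomic categories

Peak base pairs are assigned to promoter / exon / intron / intergenic by
overlap with the partition emitted by the annotation generator
(GenomicRanges does the interval arithmetic). Precedence
promoter > exon > intron > intergenic is resolved at construction time:
the partition tiles each chromosome exactly once, so no base is counted
twice. The generator reserves a 1 kb promoter upstream of each TSS
(configurable) and lets the X intergenic fraction (default 0.45) exceed
the autosomal one (0.30), reflecting the X chromosome's proportionally
larger intergenic content; uniformly placed peaks then inherit the
intergenic excess on the X, which is the qualitative behaviour the
category breakdown is meant to expose.

# Metagene profiles

Gene bodies are resampled to 100 equal-length segments by
length-weighted averaging of the bins each segment overlaps (computed
with an O(1)-per-segment cumulative-integral representation of the
track), with 1 kb flanks split into 20 fixed-width bins on each side;
minus-strand genes are reversed so the TSS is always on the left, and a
stratum profile is the unweighted mean over its genes (each expressed
gene counts once, matching an "average over expressed genes" reading;
body_bins = 100 and flank_bins = 20 are package choices since no values
are prescribed). Overlapping genes both contribute; no masking is
applied. Expression quartiles are cut at the quartile boundaries with
ties going to the lower quartile; fully tied expression falls back to a
deterministic rank-based split so quartiles stay equal-sized. The
TSS-upstream score is the mean z over [TSS-500, TSS) in strand
orientation, clipped (and flagged) at chromosome edges.

# Expression statistics

## RPKM and the X:A ratio

RPKM = count x 1e9 / (exonic length x library size), averaged over
replicates. The X:A statistic filters to genes with mean RPKM > 1 and
takes the ratio of the median X RPKM to the median autosomal RPKM.

## Contrasts and shift tests

Per-gene log2 ratios between two conditions are computed on
library-size-normalized replicate means with a pseudocount of 1 on the
normalized-count scale (at the simulated depths the pseudocount bias on
a median of ~2000-count genes is negligible, which is why the contrast
is taken on normalized counts rather than RPKM). Direction-specific
chromosome-level shifts are tested with a one-sided Wilcoxon rank-sum
test of X-linked ratios against pooled autosomal ratios (and each
autosome), using the normal approximation with tie and continuity
corrections, or exact enumeration when both groups have at most eight
observations. Differential-expression models (dispersion shrinkage,
per-gene significance) are out of scope by design: the questions asked
are about ratio distributions, so the statistics here are distributional.

## Quadrant concordance and top sets

Two contrasts sharing a gene universe are classified into quadrants by
sign pattern when |log2 ratio| exceeds 0.1 on both axes, with
percentages over all genes of each chromosome class. "Top p%" X gene
sets are ranked by descending log2 ratio in a reference contrast (ties
broken by gene id for determinism — the original ranking metric is not
stated, and fold change is the natural distribution-level choice) and
summarized in a companion contrast by median and quartiles.

## Synthetic counts

`gen_expression_counts()` draws per-gene baseline expression from a
lognormal (meanlog log 50, sdlog 0.45), multiplies X-linked baselines by
the planted X:A ratio, applies per-condition per-gene log2 effects drawn
from chromosome-class Gaussians, and emits negative-binomial counts with
var = mu + 0.05 mu^2 at 3 replicates of 3e7 reads. The baseline spread
(sdlog 0.45) is narrower than whole-transcriptome variation; it was
fixed a priori so the sampling error of an empirical median over the
~3,500 expressed X genes keeps the planted X:A ratio recoverable within
+/-0.02 at two standard errors — the generator models the filtered
expressed-gene population on which the statistic is defined, and with
this baseline essentially no gene falls below the RPKM > 1 filter, so
filter truncation does not bias the planted medians. The mild-repression
scenario uses deeper, lower-dispersion libraries (6e7, alpha = 0.02) so
the X-median standard error stays below 0.01, and the quadrant scenario
uses alpha = 0.005 with planted |effects| of at least 0.4 so
classification noise at the +/-0.1 threshold moves at most a fraction
of a percentage point of genes between quadrants. What the generator
does not model: gene-length biases of real libraries, isoforms,
correlated effects between neighbouring genes, batch structure, and
germline contamination (the larval-stage rationale for when to measure
X:A is biological, not computational).

# Scenario runner and reproducibility

`run_scenario()` executes a validated YAML config (unknown keys and
out-of-range parameters are rejected before any computation) and returns
a report whose summary numbers are all recomputed from the generated
intermediates; with `out_dir` set, per-stage tables are written as TSV
and the report as JSON. All randomness flows through one seeded
generator per call, so identical config + seed reproduces byte-identical
outputs; the caller's RNG state is left untouched. The package exposes
its pipelines as R functions plus packaged scenario configs rather than
a shell executable — `scripts/acceptance.R` is a thin Rscript over
`run_scenario()` and shows the intended batch usage.

The problem sizes used by the packaged scenarios are the study's own
group sizes (20-40 nuclei per FISH group, 16-20 nuclei per distance
group, 1e6 reads for read-fraction ratios, 2e7 reads for the peak
scenario, ~3,500 X and ~16,500 autosomal genes at 3 replicates for the
expression scenarios).

# Known limitations

* The synthetic imaging model omits optics (PSF, chromatic shift, depth
  attenuation); recovery tests validate the measurement chain only.
* The broad-peak caller is a simplified run-merge-filter scheme
  calibrated on synthetic truth; it is not a reimplementation of a
  Poisson-model caller and peak boundaries should not be compared
  against one.
* The expression module makes no per-gene significance calls; it
  quantifies distribution-level skew.
* Greedy spot pairing assumes spot pairs are far apart relative to the
  pair separation, which holds for the generator and for well-separated
  homolog territories but not for arbitrary spot clouds.
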