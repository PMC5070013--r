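#' Call broad peaks from a z-scored track
#'
#' Simplified broad-peak caller: maximal runs of bins with z >= `z_min`
#' become candidate peaks; candidates separated by less than `merge_gap`
#' bp are merged; merged peaks shorter than `min_len` bp are dropped.
#' The mean z over the bins spanned by each final peak is reported.
#'
#' @param ztrack a `zscore` [coverage_track].
#' @param z_min z threshold (> 0).
#' @param merge_gap maximum gap (bp) across which candidate runs merge.
#' @param min_len minimum peak length (bp).
#' @return A `peak_set`: data.frame (chrom, start, end, mean_z), sorted
#'   and non-overlapping within chromosomes, 0-based half-open.
#' @export
call_broad_peaks <- function(ztrack, z_min = 2.5, merge_gap = 500,
                             min_len = 200) {
  stopifnot(inherits(ztrack, "coverage_track"))
  if (z_min <= 0) stop_("z_min must be > 0")
  bs <- ztrack$bin_size
  out <- lapply(names(ztrack$values), function(ch) {
    z <- ztrack$values[[ch]]
    len <- ztrack$chrom_lengths[[ch]]
    hot <- z >= z_min
    if (!any(hot)) return(NULL)
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    s_bp <- (starts[runs] - 1) * bs
    e_bp <- pmin(ends[runs] * bs, len)
    # merge runs separated by < merge_gap
    ms <- s_bp[1L]; me <- e_bp[1L]
    merged_s <- numeric(0); merged_e <- numeric(0)
    if (length(runs) > 1L) {
      for (i in 2L:length(runs)) {
        if (s_bp[i] - me < merge_gap) {
          me <- e_bp[i]
        } else {
          merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
          ms <- s_bp[i]; me <- e_bp[i]
        }
      }
    }
    merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
    keep <- (merged_e - merged_s) >= min_len
    if (!any(keep)) return(NULL)
    merged_s <- merged_s[keep]; merged_e <- merged_e[keep]
    mean_z <- vapply(seq_along(merged_s), function(i) {
      b1 <- merged_s[i] %/% bs + 1L
      b2 <- min(ceiling(merged_e[i] / bs), length(z))
      mean(z[b1:b2])
    }, 0)
    data.frame(chrom = ch, start = merged_s, end = merged_e,
               mean_z = mean_z, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_z = numeric(0))
  }
  rownames(res) <- NULL
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Read-fraction to genome-fraction ratio per chromosome
#'
#' For each chromosome, the fraction of reads mapping to it divided by
#' its copy-weighted genome fraction (length x copy number over the
#' copy-weighted genome total). Mitochondrial reads and sequence are
#' excluded from both numerator and denominator. Under uniform per-copy
#' read density the ratio is 1 for every chromosome in any karyotype;
#' DCC-mediated depletion of the hermaphrodite X pushes its ratio well
#' below 1.
#'
#' @param reads data.frame with a chrom column (read intervals).
#' @param karyotype a [karyotype].
#' @return data.frame: chrom, n_reads, read_fraction, genome_fraction,
#'   ratio.
#' @export
read_fraction_ratio <- function(reads, karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (nrow(reads) == 0L) stop_("empty read set")
  gf <- genome_fraction(karyotype)
  keep <- reads$chrom %in% names(gf)
  n <- table(factor(reads$chrom[keep], levels = names(gf)))
  total <- sum(n)
  if (total == 0L) stop_("no reads on non-mitochondrial chromosomes")
  frac <- as.numeric(n) / total
  data.frame(chrom = names(gf), n_reads = as.numeric(n),
             read_fraction = frac,
             genome_fraction = as.numeric(gf),
             ratio = frac / as.numeric(gf),
             stringsAsFactors = FALSE)
}

#' Peak density per chromosome (peaks/Mb)
#'
#' Peak counts per megabase per chromosome, plus the X density and the
#' pooled autosomal density (total autosomal peaks over total autosomal
#' Mb). Mitochondrial chromosomes are excluded.
#'
#' @param peaks a `peak_set` (or data.frame with a chrom column).
#' @param karyotype a [karyotype].
#' @return list with `per_chromosome` (chrom, n_peaks, length_mb,
#'   peaks_per_mb), `x_density` and `autosome_density`.
#' @export
peak_density <- function(peaks, karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype[!karyotype$is_mito, , drop = FALSE]
  n <- table(factor(peaks$chrom, levels = k$chrom))
  mb <- k$length_bp / 1e6
  per <- data.frame(chrom = k$chrom, n_peaks = as.numeric(n),
                    length_mb = mb,
                    peaks_per_mb = as.numeric(n) / mb,
                    stringsAsFactors = FALSE)
  auto <- !k$is_x
  list(per_chromosome = per,
       x_density = per$peaks_per_mb[k$is_x],
       autosome_density = sum(per$n_peaks[auto]) / sum(mb[auto]))
}
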