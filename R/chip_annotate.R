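#' Assign peak base pairs to genomic categories
#'
#' Overlaps peaks with the promoter/exon/intron/intergenic partition of
#' the genome and reports, separately for the X and the pooled autosomes,
#' the fraction of peak bp falling in each category, next to the genome's
#' own category bp fractions. Because the partition tiles the genome and
#' categories never overlap, the precedence promoter > exon > intron >
#' intergenic is resolved at annotation-construction time. Peaks
#' extending past a chromosome end are clipped (with a message).
#'
#' @param peaks a `peak_set` from [call_broad_peaks()].
#' @param annotation a `genome_annotation`.
#' @return A `category_breakdown`: list with `peaks` and `genome`
#'   data.frames (class x category bp and fractions); each fraction set
#'   sums to 1.
#' @export
annotate_peaks <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  k <- annotation$karyotype
  lens <- stats::setNames(k$length_bp, k$chrom)
  x_chrom <- k$chrom[k$is_x]
  keep <- peaks$chrom %in% k$chrom[!k$is_mito]
  pk <- peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) stop_("no peaks on annotated chromosomes")
  over <- pk$end > lens[pk$chrom]
  if (any(over)) {
    message(sprintf("annotate_peaks: clipped %d peak(s) at chromosome ends",
                    sum(over)))
    pk$end <- pmin(pk$end, lens[pk$chrom])
    pk <- pk[pk$end > pk$start, , drop = FALSE]
  }
  part <- annotation$partition[!annotation$partition$chrom %in%
                                 k$chrom[k$is_mito], , drop = FALSE]
  cats <- c("promoter", "exon", "intron", "intergenic")

  pk_gr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1, pk$end))
  part_gr <- GenomicRanges::GRanges(part$chrom,
                                    IRanges::IRanges(part$start + 1, part$end))
  hits <- GenomicRanges::findOverlaps(pk_gr, part_gr)
  ov <- GenomicRanges::pintersect(pk_gr[S4Vectors::queryHits(hits)],
                                  part_gr[S4Vectors::subjectHits(hits)])
  bp <- GenomicRanges::width(ov)
  cls <- ifelse(pk$chrom[S4Vectors::queryHits(hits)] == x_chrom,
                "X", "autosome")
  cat_hit <- part$category[S4Vectors::subjectHits(hits)]
  peak_bp <- tapply(bp,
                    list(factor(cls, c("X", "autosome")),
                         factor(cat_hit, cats)), sum)
  peak_bp[is.na(peak_bp)] <- 0

  gcls <- ifelse(part$chrom == x_chrom, "X", "autosome")
  gen_bp <- tapply(part$end - part$start,
                   list(factor(gcls, c("X", "autosome")),
                        factor(part$category, cats)), sum)
  gen_bp[is.na(gen_bp)] <- 0

  to_df <- function(m) {
    out <- data.frame(class = rep(rownames(m), ncol(m)),
                      category = rep(colnames(m), each = nrow(m)),
                      bp = as.vector(m), stringsAsFactors = FALSE)
    tot <- tapply(out$bp, out$class, sum)
    out$fraction <- out$bp / as.numeric(tot[out$class])
    out
  }
  structure(list(peaks = to_df(peak_bp), genome = to_df(gen_bp)),
            class = "category_breakdown")
}

#' @export
print.category_breakdown <- function(x, ...) {
  cat("peak bp by genomic category:\n")
  print.data.frame(x$peaks, row.names = FALSE, digits = 3)
  cat("genome bp by category:\n")
  print.data.frame(x$genome, row.names = FALSE, digits = 3)
  invisible(x)
}
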