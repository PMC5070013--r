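#' Generate a synthetic genome annotation
#'
#' Lays out non-overlapping gene models along each non-mitochondrial
#' chromosome and derives the promoter / exon / intron / intergenic
#' partition that tiles every chromosome exactly once. Each gene gets a
#' TSS, a TTS, at least one exon and a strand; the promoter is the
#' `promoter_bp` window immediately 5' of the TSS on the gene's strand.
#' The intergenic fraction is configurable separately for the X and the
#' autosomes because the X chromosome carries proportionally more
#' intergenic sequence than autosomes, a feature the peak-annotation
#' analyses depend on.
#'
#' All coordinates are 0-based half-open.
#'
#' @param karyotype a [karyotype] object.
#' @param genes_per_mb gene density (genes per megabase); default 200,
#'   about the density of the C. elegans protein-coding gene set.
#' @param intergenic_frac named numeric with entries `autosome` and `X`:
#'   target fraction of each chromosome that is intergenic (excluding
#'   promoters).
#' @param promoter_bp promoter width upstream of each TSS (bp).
#' @param seed RNG seed; identical inputs give byte-identical annotations.
#' @return A `genome_annotation` object: list with elements `karyotype`,
#'   `genes` (gene_id, chrom, start, end, strand, tss, tts, n_exons,
#'   exonic_bp), `exons`, and `partition` (chrom, start, end, category).
#' @export
gen_genome_annotation <- function(karyotype,
                                  genes_per_mb = 200,
                                  intergenic_frac = c(autosome = 0.30, X = 0.45),
                                  promoter_bp = 1000,
                                  seed = 1) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (!is.numeric(genes_per_mb) || genes_per_mb <= 0) {
    stop_("genes_per_mb must be positive")
  }
  genes_per_mb <- as.numeric(genes_per_mb)
  if (!all(c("autosome", "X") %in% names(intergenic_frac))) {
    stop_("intergenic_frac needs named entries 'autosome' and 'X'")
  }
  if (any(intergenic_frac <= 0) || any(intergenic_frac >= 0.9)) {
    stop_("intergenic_frac entries must lie in (0, 0.9)")
  }
  min_body <- 150L  # smallest gene body we will lay out

  with_seed(seed, {
    gene_rows <- list()
    exon_rows <- list()
    part_rows <- list()
    for (ci in seq_len(nrow(karyotype))) {
      chrom <- karyotype$chrom[ci]
      len <- as.numeric(karyotype$length_bp[ci])
      if (karyotype$is_mito[ci]) {
        part_rows[[chrom]] <- data.frame(
          chrom = chrom, start = 0, end = len,
          category = "intergenic", stringsAsFactors = FALSE)
        next
      }
      igf <- unname(intergenic_frac[[if (karyotype$is_x[ci]) "X" else "autosome"]])
      n_genes <- as.integer(round(genes_per_mb * len / 1e6))
      min_slot <- ceiling((promoter_bp + min_body) / (1 - igf))
      if (n_genes < 1L || len < min_slot) {
        stop_(sprintf(
          "chromosome %s (%d bp) is too short to host one gene at %g genes/Mb",
          chrom, len, genes_per_mb))
      }
      slot <- len %/% n_genes
      slot_start <- (seq_len(n_genes) - 1L) * slot
      slot_len <- rep(slot, n_genes)
      slot_len[n_genes] <- len - slot_start[n_genes]

      # jitter the intergenic budget per slot so gene lengths vary while
      # the chromosome-level intergenic fraction stays near its target
      igf_i <- pmin(0.85, pmax(0.05, igf * stats::runif(n_genes, 0.6, 1.4)))
      ig_tot <- pmax(2L, as.integer(round(igf_i * slot_len)))
      body <- slot_len - ig_tot - promoter_bp
      if (any(body < min_body)) {
        stop_(sprintf(
          "chromosome %s slots too short for gene bodies; lower genes_per_mb or intergenic_frac",
          chrom))
      }
      gap_left <- pmax(1L, as.integer(round(ig_tot * stats::runif(n_genes, 0.25, 0.75))))
      gap_right <- ig_tot - gap_left
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)

      # slot layout: [gap_left][promoter][body][gap_right] on '+',
      # mirrored ([gap_left][body][promoter][gap_right]) on '-'
      body_start <- slot_start + gap_left +
        ifelse(strand == "+", promoter_bp, 0L)
      body_end <- body_start + body
      prom_start <- ifelse(strand == "+", body_start - promoter_bp, body_end)
      prom_end <- prom_start + promoter_bp
      tss <- ifelse(strand == "+", body_start, body_end)
      tts <- ifelse(strand == "+", body_end, body_start)

      gene_id <- sprintf("%s_g%05d", chrom, seq_len(n_genes))

      # exon/intron structure: n_ex exons separated by n_ex - 1 introns
      n_ex <- 1L + stats::rpois(n_genes, 2)
      n_ex <- pmin(n_ex, pmax(1L, body %/% 100L))
      # per-gene exon/intron segmentation, accumulated as flat vectors
      nseg_all <- 2L * n_ex - 1L
      seg_gene <- rep.int(seq_len(n_genes), nseg_all)
      seg_pos <- sequence(nseg_all)
      seg_len <- integer(length(seg_gene))
      off <- 0L
      for (g in seq_len(n_genes)) {
        nseg <- nseg_all[g]
        seg_len[off + seq_len(nseg)] <- if (nseg == 1L) {
          body[g]
        } else {
          as.vector(stats::rmultinom(1L, body[g] - nseg, rep(1, nseg))) + 1L
        }
        off <- off + nseg
      }
      cs <- cumsum(seg_len)
      before_gene <- c(0, cs[cumsum(nseg_all)])[seg_gene]
      seg_end <- body_start[seg_gene] + (cs - before_gene)
      seg_start <- seg_end - seg_len
      is_exon <- seg_pos %% 2L == 1L
      exons <- data.frame(
        gene_id = gene_id[seg_gene[is_exon]], chrom = chrom,
        start = seg_start[is_exon], end = seg_end[is_exon],
        stringsAsFactors = FALSE)
      exonic_bp <- as.numeric(
        tapply(seg_len[is_exon], seg_gene[is_exon], sum))
      in_list <- if (any(!is_exon)) {
        list(data.frame(start = seg_start[!is_exon], end = seg_end[!is_exon],
                        category = "intron", stringsAsFactors = FALSE))
      } else {
        list()
      }

      gene_rows[[chrom]] <- data.frame(
        gene_id = gene_id, chrom = chrom,
        start = body_start, end = body_end, strand = strand,
        tss = tss, tts = tts, n_exons = n_ex, exonic_bp = exonic_bp,
        stringsAsFactors = FALSE)
      exon_rows[[chrom]] <- exons

      # partition: everything not promoter/exon/intron is intergenic
      feat <- rbind(
        data.frame(start = prom_start, end = prom_end,
                   category = "promoter", stringsAsFactors = FALSE),
        data.frame(start = exons$start, end = exons$end,
                   category = "exon", stringsAsFactors = FALSE))
      intr <- do.call(rbind, in_list[!vapply(in_list, is.null, TRUE)])
      if (!is.null(intr) && nrow(intr) > 0L) feat <- rbind(feat, intr)
      feat <- feat[order(feat$start), , drop = FALSE]
      gaps_start <- c(0, feat$end)
      gaps_end <- c(feat$start, len)
      keep <- gaps_end > gaps_start
      part <- rbind(
        feat,
        data.frame(start = gaps_start[keep], end = gaps_end[keep],
                   category = "intergenic", stringsAsFactors = FALSE))
      part <- part[order(part$start), , drop = FALSE]
      part_rows[[chrom]] <- data.frame(chrom = chrom, part,
                                       stringsAsFactors = FALSE)
    }
    ann <- structure(list(
      karyotype = karyotype,
      genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
      exons = do.call(rbind, c(exon_rows, list(make.row.names = FALSE))),
      partition = do.call(rbind, c(part_rows, list(make.row.names = FALSE))),
      params = list(genes_per_mb = genes_per_mb,
                    intergenic_frac = intergenic_frac,
                    promoter_bp = promoter_bp, seed = seed)),
      class = "genome_annotation")
    validate_partition(ann)
    ann
  })
}

# Invariant check: the category partition tiles each chromosome exactly.
validate_partition <- function(ann) {
  for (ci in seq_len(nrow(ann$karyotype))) {
    chrom <- ann$karyotype$chrom[ci]
    p <- ann$partition[ann$partition$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    ok <- nrow(p) > 0L && p$start[1L] == 0 &&
      p$end[nrow(p)] == ann$karyotype$length_bp[ci] &&
      all(p$end > p$start) &&
      (nrow(p) == 1L || all(p$start[-1L] == p$end[-nrow(p)]))
    if (!ok) stop_(sprintf("internal error: partition does not tile %s", chrom))
  }
  invisible(ann)
}

#' Category bp fractions of the genome partition
#'
#' @param annotation a `genome_annotation`.
#' @param chroms optional subset of chromosome names (mitochondrial
#'   chromosomes are dropped by default).
#' @return Named numeric vector of bp fractions over
#'   promoter/exon/intron/intergenic, summing to 1.
#' @export
partition_fractions <- function(annotation, chroms = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  k <- annotation$karyotype
  keep <- k$chrom[!k$is_mito]
  if (!is.null(chroms)) keep <- intersect(keep, chroms)
  p <- annotation$partition[annotation$partition$chrom %in% keep, , drop = FALSE]
  bp <- tapply(p$end - p$start, factor(p$category,
               levels = c("promoter", "exon", "intron", "intergenic")), sum)
  bp[is.na(bp)] <- 0
  c(bp / sum(bp))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosomes (%.0f genes/Mb)\n",
              nrow(x$genes), nrow(x$karyotype), x$params$genes_per_mb))
  invisible(x)
}
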