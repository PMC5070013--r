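# Gene-anchored profiles of ChIP enrichment: scaled gene bodies with
# fixed-width flanks, stratified by chromosome class, expression quartile
# or arbitrary gene sets.

# Cumulative integral of a per-bin step function, evaluated at arbitrary
# bp positions (clipped to [0, len]). Lets segment means be computed in
# O(1) per segment: mean over [a, b) = (C(b) - C(a)) / (b - a).
track_integral <- function(values, bin_size, len) {
  cum <- c(0, cumsum(values) * bin_size)
  nb <- length(values)
  function(x) {
    x <- pmax(0, pmin(x, len))
    i <- pmin(floor(x / bin_size), nb - 1)
    cum[i + 1] + (x - i * bin_size) * values[i + 1]
  }
}

# Per-gene profile: flank_bins upstream segments (flank_bp total), body
# resampled to body_bins segments, flank_bins downstream. Minus-strand
# genes are reversed so the TSS is always on the left. Out-of-chromosome
# flank segments are NA.
gene_profile <- function(Cfun, len, start, end, strand,
                         flank_bp, body_bins, flank_bins) {
  up <- seq(start - flank_bp, start, length.out = flank_bins + 1)
  body <- seq(start, end, length.out = body_bins + 1)
  down <- seq(end, end + flank_bp, length.out = flank_bins + 1)
  bounds <- c(up, body[-1], down[-1])
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1]
  clo <- pmax(lo, 0); chi <- pmin(hi, len)
  w <- chi - clo
  val <- ifelse(w > 0, (Cfun(chi) - Cfun(clo)) / pmax(w, 1e-12), NA_real_)
  if (strand == "-") val <- rev(val)
  val
}

#' Metagene profile of enrichment across gene bodies
#'
#' Computes the average z-scored enrichment across gene bodies scaled to
#' a fixed number of bins, with fixed-width upstream/downstream flanks
#' (1 kb by default), for one or more gene strata. Each gene body is
#' resampled to `body_bins` segments by length-weighted averaging of the
#' track bins it spans; minus-strand genes are reversed so the TSS is on
#' the left; the stratum profile is the unweighted mean over its genes.
#' Genes shorter than `body_bins` bp are skipped with a message.
#'
#' @param track a `zscore` (or any) [coverage_track].
#' @param genes data.frame with gene_id, chrom, start, end, strand
#'   (e.g. the `genes` element of a `genome_annotation`).
#' @param strata named list of gene_id vectors; default splits genes
#'   into X vs autosome using the track's chromosome names and an `is_x`
#'   attribute is not required (stratum = chromosome class).
#' @param x_chrom name of the X chromosome (for the default strata).
#' @param flank_bp flank width in bp on each side.
#' @param body_bins number of scaled gene-body bins.
#' @param flank_bins number of bins per flank.
#' @return data.frame of class `metagene_profile`: stratum, position
#'   (1..2*flank_bins+body_bins), region (upstream/body/downstream),
#'   z_mean, n_genes.
#' @export
metagene_profile <- function(track, genes, strata = NULL, x_chrom = "X",
                             flank_bp = 1000, body_bins = 100,
                             flank_bins = 20) {
  stopifnot(inherits(track, "coverage_track"))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop_("genes need columns gene_id, chrom, start, end, strand")
  }
  genes <- genes[genes$chrom %in% names(track$values), , drop = FALSE]
  too_short <- (genes$end - genes$start) < body_bins
  if (any(too_short)) {
    message(sprintf("metagene_profile: skipped %d gene(s) shorter than %d bp",
                    sum(too_short), body_bins))
    genes <- genes[!too_short, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop_("no usable genes")
  if (is.null(strata)) {
    strata <- split(genes$gene_id, ifelse(genes$chrom == x_chrom,
                                          "X", "autosome"))
  }
  n_pos <- 2L * flank_bins + body_bins
  region <- rep(c("upstream", "body", "downstream"),
                c(flank_bins, body_bins, flank_bins))

  # one profile row per gene, computed once, then averaged per stratum
  Cfuns <- lapply(names(track$values), function(ch) {
    track_integral(track$values[[ch]], track$bin_size,
                   track$chrom_lengths[[ch]])
  })
  names(Cfuns) <- names(track$values)
  prof <- matrix(NA_real_, nrow(genes), n_pos)
  for (g in seq_len(nrow(genes))) {
    prof[g, ] <- gene_profile(Cfuns[[genes$chrom[g]]],
                              track$chrom_lengths[[genes$chrom[g]]],
                              genes$start[g], genes$end[g], genes$strand[g],
                              flank_bp, body_bins, flank_bins)
  }
  rownames(prof) <- genes$gene_id

  out <- lapply(names(strata), function(sn) {
    ids <- intersect(strata[[sn]], genes$gene_id)
    if (length(ids) == 0L) return(NULL)
    m <- prof[ids, , drop = FALSE]
    data.frame(stratum = sn, position = seq_len(n_pos), region = region,
               z_mean = colMeans(m, na.rm = TRUE), n_genes = length(ids),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("metagene_profile", "data.frame")
  res
}

#' Metagene profiles stratified by expression quartile
#'
#' Splits genes at the quartile boundaries of their expression (ties
#' assigned to the lower quartile) and computes one metagene profile per
#' quartile, separately for X and autosomes when `by_class` is set.
#'
#' @param track a [coverage_track].
#' @param genes gene table (see [metagene_profile()]).
#' @param expression data.frame with gene_id and mean_rpkm.
#' @param by_class split into X vs autosome classes as well.
#' @param x_chrom X chromosome name.
#' @param ... passed to [metagene_profile()].
#' @return `metagene_profile` data.frame with strata like `X.Q1`.
#' @export
quartile_profiles <- function(track, genes, expression, by_class = TRUE,
                              x_chrom = "X", ...) {
  m <- merge(genes, expression[, c("gene_id", "mean_rpkm")], by = "gene_id")
  if (nrow(m) < 4L) stop_("need at least 4 genes with expression values")
  qs <- stats::quantile(m$mean_rpkm, c(0.25, 0.5, 0.75))
  qlab <- if (anyDuplicated(qs)) {
    # heavily tied expression: split deterministically by rank so the
    # quartiles stay (near-)equal sized
    r <- rank(m$mean_rpkm, ties.method = "first")
    factor(paste0("Q", ceiling(4 * r / nrow(m))),
           levels = c("Q1", "Q2", "Q3", "Q4"))
  } else {
    # ties at a boundary go to the lower quartile (right-closed cut)
    cut(m$mean_rpkm, c(-Inf, qs, Inf),
        labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  }
  key <- if (by_class) {
    paste(ifelse(m$chrom == x_chrom, "X", "autosome"), qlab, sep = ".")
  } else {
    as.character(qlab)
  }
  strata <- split(m$gene_id, key)
  metagene_profile(track, genes, strata = strata, x_chrom = x_chrom, ...)
}

#' Mean enrichment in a window upstream of each TSS
#'
#' Average track value over [TSS - window, TSS) in the gene's strand
#' orientation (downstream of the TTS is never touched). Windows running
#' past a chromosome edge are clipped to the available part and flagged.
#'
#' @param track a [coverage_track].
#' @param genes gene table with tss and strand columns.
#' @param window window width in bp.
#' @return data.frame: gene_id, score, clipped.
#' @export
tss_upstream_score <- function(track, genes, window = 500) {
  stopifnot(inherits(track, "coverage_track"))
  genes <- genes[genes$chrom %in% names(track$values), , drop = FALSE]
  out <- vector("list", length(track$values))
  for (ch in names(track$values)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    len <- track$chrom_lengths[[ch]]
    Cfun <- track_integral(track$values[[ch]], track$bin_size, len)
    a <- ifelse(g$strand == "+", g$tss - window, g$tss)
    b <- ifelse(g$strand == "+", g$tss, g$tss + window)
    ca <- pmax(a, 0); cb <- pmin(b, len)
    w <- cb - ca
    out[[ch]] <- data.frame(
      gene_id = g$gene_id,
      score = ifelse(w > 0, (Cfun(cb) - Cfun(ca)) / pmax(w, 1e-12),
                     NA_real_),
      clipped = w < (b - a), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(genes$gene_id, res$gene_id), , drop = FALSE]
}
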