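#' RPKM expression table from a count matrix
#'
#' Computes reads-per-kilobase-per-million for each gene and replicate
#' (RPKM = count x 1e9 / (exonic length x library size)), plus the mean
#' RPKM and library-size-normalized mean count used by the contrast
#' statistics.
#'
#' @param counts integer matrix, genes x replicates (rownames = gene ids).
#' @param genes data.frame with gene_id, chrom, exonic_bp (gene order
#'   must match the count rows).
#' @param library_sizes per-replicate library sizes; defaults to the
#'   column sums of `counts`.
#' @return An `expression_table` data.frame: gene_id, chrom, exonic_bp,
#'   mean_count, norm_mean (library-size-normalized mean count),
#'   mean_rpkm; per-replicate RPKM as attribute `rpkm`.
#' @export
compute_rpkm <- function(counts, genes, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(genes)) {
    stop_("counts and genes must have one row per gene, in the same order")
  }
  if (any(library_sizes <= 0)) stop_("library sizes must be > 0")
  if (any(genes$exonic_bp <= 0)) stop_("gene exonic lengths must be > 0")
  library_sizes <- rep_len(as.numeric(library_sizes), ncol(counts))
  rpkm <- sweep(counts, 2L, library_sizes, `/`) * 1e9 / genes$exonic_bp
  # per-replicate counts rescaled to the mean library size, then averaged
  norm <- sweep(counts, 2L, library_sizes / mean(library_sizes), `/`)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    exonic_bp = genes$exonic_bp,
                    mean_count = rowMeans(counts),
                    norm_mean = rowMeans(norm),
                    mean_rpkm = rowMeans(rpkm),
                    stringsAsFactors = FALSE)
  attr(out, "rpkm") <- rpkm
  attr(out, "library_sizes") <- library_sizes
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Median X:A expression ratio
#'
#' Filters to expressed genes (mean RPKM above `min_rpkm`), then divides
#' the median RPKM of X-linked genes by the median RPKM of autosomal
#' genes. Per-chromosome medians are returned alongside; each of those is
#' also expressed relative to the pooled autosomal median.
#'
#' @param table an `expression_table`.
#' @param x_chrom X chromosome name.
#' @param min_rpkm expression filter (default 1).
#' @param exclude optional chromosomes to drop (e.g. mitochondrial).
#' @return list: `ratio` (median X / median autosome),
#'   `per_chromosome` (chrom, n, median_rpkm, ratio_to_autosome),
#'   `n_x`, `n_autosome`.
#' @export
median_xa_ratio <- function(table, x_chrom = "X", min_rpkm = 1,
                            exclude = "MtDNA") {
  stopifnot(inherits(table, "data.frame"))
  t <- table[table$mean_rpkm > min_rpkm &
               !(table$chrom %in% exclude), , drop = FALSE]
  on_x <- t$chrom == x_chrom
  if (!any(on_x)) stop_("no expressed X-linked genes after filtering")
  if (all(on_x)) stop_("no expressed autosomal genes after filtering")
  med_x <- stats::median(t$mean_rpkm[on_x])
  med_a <- stats::median(t$mean_rpkm[!on_x])
  per <- do.call(rbind, lapply(split(t$mean_rpkm, t$chrom), function(v) {
    data.frame(n = length(v), median_rpkm = stats::median(v))
  }))
  per <- data.frame(chrom = rownames(per), per,
                    ratio_to_autosome = per$median_rpkm / med_a,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(ratio = med_x / med_a, per_chromosome = per,
       n_x = sum(on_x), n_autosome = sum(!on_x))
}

#' Per-gene log2 expression ratios between two conditions
#'
#' log2((A + pseudocount) / (B + pseudocount)) on the library-size-
#' normalized replicate means of the two conditions, over the shared gene
#' universe. Swapping the conditions negates every ratio.
#'
#' @param table_a,table_b `expression_table`s for condition and control.
#' @param pseudocount added to both normalized means (count scale).
#' @param min_rpkm optional expression filter applied to both tables
#'   (genes must exceed it in both conditions); `NULL` disables.
#' @return A `contrast_result` data.frame: gene_id, chrom, log2_ratio.
#' @export
contrast_log2 <- function(table_a, table_b, pseudocount = 1,
                          min_rpkm = NULL) {
  shared <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(shared) == 0L) stop_("no shared genes between conditions")
  a <- table_a[match(shared, table_a$gene_id), ]
  b <- table_b[match(shared, table_b$gene_id), ]
  if (!is.null(min_rpkm)) {
    keep <- a$mean_rpkm > min_rpkm & b$mean_rpkm > min_rpkm
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
  }
  out <- data.frame(gene_id = a$gene_id, chrom = a$chrom,
                    log2_ratio = log2((a$norm_mean + pseudocount) /
                                      (b$norm_mean + pseudocount)),
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Chromosome-level shift tests on a contrast
#'
#' One-sided Wilcoxon rank-sum tests of the X-linked log2 ratios against
#' the pooled autosomal ratios, and against each autosome separately, in
#' the stated direction (`"greater"` for derepression of X, `"less"` for
#' repression).
#'
#' @param contrast a `contrast_result`.
#' @param direction `"greater"` or `"less"` (X relative to autosomes).
#' @param x_chrom X chromosome name.
#' @param exclude chromosomes to drop.
#' @param min_n minimum genes per group (default 5).
#' @return data.frame: comparison, n_x, n_other, statistic, p_value.
#' @export
chromosome_shift_test <- function(contrast, direction = c("greater", "less"),
                                  x_chrom = "X", exclude = "MtDNA",
                                  min_n = 5L) {
  direction <- match.arg(direction)
  d <- contrast[!(contrast$chrom %in% exclude), , drop = FALSE]
  xv <- d$log2_ratio[d$chrom == x_chrom]
  autosomes <- setdiff(unique(d$chrom), x_chrom)
  if (length(xv) < min_n) stop_(sprintf("fewer than %d X genes", min_n))
  comparisons <- c("autosomes", autosomes)
  out <- lapply(comparisons, function(cmp) {
    ov <- if (cmp == "autosomes") {
      d$log2_ratio[d$chrom != x_chrom]
    } else {
      d$log2_ratio[d$chrom == cmp]
    }
    if (length(ov) < min_n) return(NULL)
    res <- wilcoxon_rank_sum(xv, ov, alternative = direction)
    data.frame(comparison = paste0("X_vs_", cmp),
               n_x = length(xv), n_other = length(ov),
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quadrant classification of two contrasts
#'
#' Places each gene of the shared universe in one of four quadrants of
#' the (contrast A, contrast B) plane when its |log2 ratio| exceeds the
#' threshold on both axes, otherwise leaves it unclassified, and reports
#' the percentage of X-linked and autosomal genes per quadrant. Quadrant
#' labels are sign patterns `up_up`, `up_down`, `down_up`, `down_down`
#' (A first). With `denominator = "all"` (default) percentages are over
#' all genes of the class, so the five percentages sum to 100.
#'
#' @param contrast_a,contrast_b `contrast_result`s on a shared universe.
#' @param threshold |log2| threshold for quadrant membership (default
#'   0.1, i.e. a >10\% expression change on both axes).
#' @param x_chrom X chromosome name.
#' @param exclude chromosomes to drop.
#' @param denominator `"all"` or `"classified"`.
#' @return A `quadrant_table` data.frame: class, quadrant, n, percent;
#'   attribute `threshold`.
#' @export
quadrant_classify <- function(contrast_a, contrast_b, threshold = 0.1,
                              x_chrom = "X", exclude = "MtDNA",
                              denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  m <- merge(contrast_a[, c("gene_id", "chrom", "log2_ratio")],
             contrast_b[, c("gene_id", "log2_ratio")],
             by = "gene_id", suffixes = c("_a", "_b"))
  m <- m[!(m$chrom %in% exclude), , drop = FALSE]
  if (nrow(m) == 0L) stop_("no shared genes to classify")
  in_quad <- abs(m$log2_ratio_a) > threshold & abs(m$log2_ratio_b) > threshold
  quad <- rep("unclassified", nrow(m))
  quad[in_quad] <- paste0(ifelse(m$log2_ratio_a[in_quad] > 0, "up", "down"),
                          "_",
                          ifelse(m$log2_ratio_b[in_quad] > 0, "up", "down"))
  cls <- ifelse(m$chrom == x_chrom, "X", "autosome")
  levels_q <- c("up_up", "up_down", "down_up", "down_down", "unclassified")
  tab <- table(factor(cls, c("X", "autosome")), factor(quad, levels_q))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("class", "quadrant", "n")
  denom <- if (denominator == "all") {
    rowSums(tab)
  } else {
    rowSums(tab[, levels_q != "unclassified", drop = FALSE])
  }
  out$percent <- 100 * out$n / as.numeric(denom[out$class])
  out <- out[order(match(out$class, c("X", "autosome")),
                   match(out$quadrant, levels_q)), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("quadrant_table", "data.frame")
  out
}

#' Top differentially expressed gene sets and companion distributions
#'
#' Ranks the X-linked genes of a reference contrast by descending log2
#' ratio (ties broken by gene id for determinism), extracts the top p\%
#' sets, and summarizes the same genes' ratios in a companion contrast
#' (median and quartiles), next to the all-X baseline.
#'
#' @param reference a `contrast_result` used for ranking.
#' @param companion a `contrast_result` in which the sets are evaluated.
#' @param pcts percentages (default 5, 10, 15).
#' @param x_chrom chromosome whose genes are ranked.
#' @return list: `sets` (named list of gene_id vectors) and `summary`
#'   (data.frame: set, n, companion median/q1/q3).
#' @export
top_percent_sets <- function(reference, companion, pcts = c(5, 10, 15),
                             x_chrom = "X") {
  ref <- reference[reference$chrom == x_chrom, , drop = FALSE]
  if (nrow(ref) < 20L) stop_("need >= 20 X-linked genes in the reference")
  ord <- order(-ref$log2_ratio, ref$gene_id)
  ref <- ref[ord, , drop = FALSE]
  comp <- companion[match(ref$gene_id, companion$gene_id), , drop = FALSE]
  summarize <- function(v, label, n) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(set = label, n = n, companion_q1 = q[[1L]],
               companion_median = q[[2L]], companion_q3 = q[[3L]],
               stringsAsFactors = FALSE)
  }
  sets <- list()
  rows <- list()
  for (p in pcts) {
    k <- max(1L, round(p / 100 * nrow(ref)))
    ids <- ref$gene_id[seq_len(k)]
    sets[[paste0("top", p)]] <- ids
    rows[[paste0("top", p)]] <-
      summarize(comp$log2_ratio[seq_len(k)], paste0("top", p, "pct"), k)
  }
  rows[["all"]] <- summarize(comp$log2_ratio, "all_x", nrow(ref))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  list(sets = sets, summary = res)
}
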