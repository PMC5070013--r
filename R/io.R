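# On-disk interchange: multi-page TIFF for image stacks (one file per
# channel plus a JSON sidecar for voxel size and intensity scale), BED /
# bedGraph / GTF through rtracklayer, TSV count tables.

#' Write an image stack as multi-page TIFF files
#'
#' One 32-bit float TIFF per channel (z slices as pages), intensities
#' scaled into [0, 1]; voxel size, channel names and the intensity scale
#' go to a JSON sidecar so [read_image_stack()] restores the stack
#' exactly.
#'
#' @param stack an [image_stack].
#' @param prefix output path prefix; files are `<prefix>_<channel>.tif`
#'   and `<prefix>_meta.json`.
#' @return invisibly, the written file paths.
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1e-12, max(vapply(stack$channels, max, 0)))
  paths <- character(0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / scale
    pages <- lapply(seq_len(dim(arr)[3L]), function(z) arr[, , z])
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    paths <- c(paths, path)
  }
  meta <- list(channels = names(stack$channels),
               voxel_size = stack$voxel_size, intensity_scale = scale)
  meta_path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}

#' Read an image stack written by [write_image_stack()]
#' @param prefix the path prefix used when writing.
#' @return an [image_stack].
#' @export
read_image_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    d <- c(dim(pages[[1L]]), length(pages))
    arr <- array(0, d)
    for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
    arr * meta$intensity_scale
  })
  names(channels) <- meta$channels
  image_stack(channels, meta$voxel_size)
}

rtracklayer_or_stop <- function() {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_("package 'rtracklayer' is required for BED/bedGraph/GTF IO")
  }
}

#' Write intervals to a BED file
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open)
#'   and optionally name/score columns.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  rtracklayer_or_stop()
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1,
                                                intervals$end))
  if (!is.null(intervals$score)) gr$score <- intervals$score
  if (!is.null(intervals$name)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval data.frame
#' @param path BED file.
#' @return data.frame chrom, start, end (plus name/score if present).
#' @export
read_bed <- function(path) {
  rtracklayer_or_stop()
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer_or_stop()
  stopifnot(inherits(track, "coverage_track"))
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- length(v)
    start <- (seq_len(nb) - 1) * track$bin_size
    end <- pmin(start + track$bin_size, track$chrom_lengths[[ch]])
    data.frame(chrom = ch, start = start, end = end, score = v,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a genome annotation as GTF
#'
#' Emits gene and exon features (1-based inclusive on disk, as GTF
#' requires) for the gene models of a `genome_annotation`.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file.
#' @export
write_gtf <- function(annotation, path) {
  rtracklayer_or_stop()
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  e <- merge(annotation$exons, g[, c("gene_id", "strand")], by = "gene_id")
  feat <- rbind(
    data.frame(chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, type = "gene", gene_id = g$gene_id,
               stringsAsFactors = FALSE),
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               strand = e$strand, type = "exon", gene_id = e$gene_id,
               stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start + 1, feat$end),
                               strand = feat$strand)
  gr$type <- feat$type
  gr$gene_id <- feat$gene_id
  gr$source <- "xdosage"
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}

#' Read gene models from a GTF file
#' @param path GTF file.
#' @return data.frame of gene features with 0-based half-open
#'   coordinates: gene_id, chrom, start, end, strand, tss, tts.
#' @export
read_gtf_genes <- function(path) {
  rtracklayer_or_stop()
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "gene"]
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, strand = strand,
             tss = ifelse(strand == "+", start0, end0),
             tts = ifelse(strand == "+", end0, start0),
             stringsAsFactors = FALSE)
}

#' Write / read a gene count table as TSV
#' @param counts gene x replicate matrix with gene ids as rownames.
#' @param path TSV file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
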