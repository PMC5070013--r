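#' Binned coverage track
#'
#' Per-chromosome per-bin values with a bin size and a semantics tag
#' recording what stage of the pipeline produced them (`raw` counts,
#' `normalized`, `input_subtracted` enrichment, or `zscore`). Bins tile
#' each chromosome in 0-based half-open coordinates; the last bin of a
#' chromosome may be short.
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param bin_size bin width in bp.
#' @param semantics one of `"raw"`, `"normalized"`, `"input_subtracted"`,
#'   `"zscore"`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @return A `coverage_track`.
#' @export
coverage_track <- function(values, bin_size, semantics, chrom_lengths) {
  stopifnot(is.list(values), !is.null(names(values)))
  semantics <- match.arg(semantics,
                         c("raw", "normalized", "input_subtracted", "zscore"))
  for (ch in names(values)) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    if (length(values[[ch]]) != nb) {
      stop_(sprintf("chromosome %s: expected %d bins, got %d",
                    ch, nb, length(values[[ch]])))
    }
  }
  structure(list(values = values, bin_size = bin_size,
                 semantics = semantics,
                 chrom_lengths = chrom_lengths[names(values)]),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s): %d chromosomes, bin %d bp, %d bins\n",
              x$semantics, length(x$values), x$bin_size,
              sum(lengths(x$values))))
  invisible(x)
}

#' Bin reads into a raw coverage track
#'
#' Counts, per fixed-width bin, the reads whose midpoint falls in the
#' bin. The sum of all bin counts equals the number of reads.
#'
#' @param reads data.frame with chrom, start, end (0-based half-open).
#' @param karyotype a [karyotype] giving chromosome lengths.
#' @param bin_size bin width in bp (>= 10).
#' @return A raw [coverage_track].
#' @export
bin_coverage <- function(reads, karyotype, bin_size = 50) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (bin_size < 10) stop_("bin_size must be >= 10 bp")
  unknown <- setdiff(unique(reads$chrom), karyotype$chrom)
  if (length(unknown)) {
    stop_(sprintf("reads on unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  lens <- stats::setNames(karyotype$length_bp, karyotype$chrom)
  mid <- floor((reads$start + reads$end) / 2)
  values <- lapply(karyotype$chrom, function(ch) {
    nb <- ceiling(lens[[ch]] / bin_size)
    sel <- reads$chrom == ch
    if (!any(sel)) return(numeric(nb))
    b <- pmin(mid[sel] %/% bin_size + 1L, nb)
    as.numeric(tabulate(b, nb))
  })
  names(values) <- karyotype$chrom
  coverage_track(values, bin_size, "raw", lens)
}

#' Ploidy-aware normalization and input subtraction
#'
#' Normalizes ChIP and input coverage to the genome-wide median bin
#' coverage (mitochondrial bins excluded) and subtracts the normalized
#' input from the normalized ChIP bin-wise to give final enrichment
#' scores. In XX mode every bin is divided by the genome-wide median. In
#' XO mode the single-copy X carries half the per-cell coverage of the
#' autosomes, so autosomal bins are divided by the median of autosomal
#' bins and X bins by half that median, putting both on the same
#' per-copy scale. The same rule is applied to the input track before
#' subtraction.
#'
#' The mode is taken from the karyotype (X copy number 2 = XX, 1 = XO).
#'
#' @param chip,input raw [coverage_track]s on the same binning.
#' @param karyotype a [karyotype].
#' @return An `input_subtracted` [coverage_track]; the normalization
#'   medians are attached as attribute `medians`.
#' @export
normalize_ploidy_aware <- function(chip, input, karyotype) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size) {
    stop_("chip and input tracks must share the same binning")
  }
  nc <- ploidy_normalize_values(chip, karyotype)
  ni <- ploidy_normalize_values(input, karyotype)
  final <- lapply(names(nc$values), function(ch) {
    nc$values[[ch]] - ni$values[[ch]]
  })
  names(final) <- names(nc$values)
  out <- coverage_track(final, chip$bin_size, "input_subtracted",
                        chip$chrom_lengths)
  attr(out, "medians") <- list(chip = nc$medians, input = ni$medians,
                               mode = nc$mode)
  out
}

# Core ploidy-aware normalization of one track (shared by
# normalize_ploidy_aware and normalize_track).
ploidy_normalize_values <- function(track, karyotype) {
  mode <- if (karyotype$copy_number[karyotype$is_x] == 2L) "XX" else "XO"
  x_chrom <- karyotype$chrom[karyotype$is_x]
  mito <- karyotype$chrom[karyotype$is_mito]
  vals <- track$values
  non_mito <- setdiff(names(vals), mito)
  if (mode == "XX") {
    m <- stats::median(unlist(vals[non_mito], use.names = FALSE))
    if (m == 0) stop_("zero genome-wide median coverage")
    out <- lapply(vals, function(v) v / m)
    meds <- c(genome = m)
  } else {
    auto <- setdiff(non_mito, x_chrom)
    m <- stats::median(unlist(vals[auto], use.names = FALSE))
    if (m == 0) stop_("zero autosomal median coverage")
    out <- lapply(names(vals), function(ch) {
      if (ch == x_chrom) vals[[ch]] / (m / 2) else vals[[ch]] / m
    })
    names(out) <- names(vals)
    meds <- c(autosome = m, x_divisor = m / 2)
  }
  list(values = out, medians = meds, mode = mode)
}

#' Normalize a single track to its genome-wide median
#'
#' The pre-subtraction normalization step on its own (useful for
#' inspecting the normalization contract: the genome-wide median of the
#' result is 1 in XX mode).
#'
#' @inheritParams normalize_ploidy_aware
#' @param track a raw [coverage_track].
#' @return A `normalized` [coverage_track].
#' @export
normalize_track <- function(track, karyotype) {
  n <- ploidy_normalize_values(track, karyotype)
  out <- coverage_track(n$values, track$bin_size, "normalized",
                        track$chrom_lengths)
  attr(out, "medians") <- n$medians
  out
}

#' Z-score standardization of enrichment scores
#'
#' Standardizes enrichment values against an estimate of the background
#' distribution. Two background definitions are available:
#' \describe{
#'   \item{all_bins_robust}{median/MAD over all non-mitochondrial bins
#'     (default). Robust to the minority of genuinely enriched bins and
#'     invariant to adding a constant to the track.}
#'   \item{nonpositive_bins}{bins with enrichment <= 0 are assumed to be
#'     the lower half of a symmetric background centred at 0; mu = 0 and
#'     sigma is estimated from the mirrored nonpositive values.}
#' }
#'
#' @param track an `input_subtracted` [coverage_track].
#' @param karyotype a [karyotype] (to exclude mitochondrial bins).
#' @param background `"all_bins_robust"` or `"nonpositive_bins"`.
#' @return A `zscore` [coverage_track] with attribute `background`
#'   recording the estimated mu and sigma.
#' @export
zscore_standardize <- function(track, karyotype,
                               background = c("all_bins_robust",
                                              "nonpositive_bins")) {
  background <- match.arg(background)
  stopifnot(inherits(track, "coverage_track"))
  mito <- karyotype$chrom[karyotype$is_mito]
  v <- unlist(track$values[setdiff(names(track$values), mito)],
              use.names = FALSE)
  if (background == "all_bins_robust") {
    if (length(v) < 100L) stop_("need >= 100 background bins")
    mu <- stats::median(v)
    sigma <- stats::mad(v)
  } else {
    bg <- v[v <= 0]
    if (length(bg) < 100L) stop_("need >= 100 nonpositive background bins")
    mu <- 0
    sigma <- stats::sd(c(bg, -bg))
  }
  if (sigma == 0) stop_("zero background spread; cannot standardize")
  out_vals <- lapply(track$values, function(x) (x - mu) / sigma)
  out <- coverage_track(out_vals, track$bin_size, "zscore",
                        track$chrom_lengths)
  attr(out, "background") <- list(definition = background, mu = mu,
                                  sigma = sigma)
  out
}
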