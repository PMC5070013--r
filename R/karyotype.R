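#' Karyotype configuration
#'
#' A karyotype records the chromosome complement of the simulated animal:
#' chromosome names, lengths, per-chromosome copy numbers and which
#' chromosome is the X. The XX/XO distinction that drives every
#' ploidy-aware computation in the package lives here: an XX hermaphrodite
#' carries two copies of X and two of each autosome, an XO animal a single
#' X. Copy-weighted genome fractions derived from the karyotype are the
#' denominators for ChIP read-fraction ratios.
#'
#' @param chrom character vector of chromosome names.
#' @param length_bp positive integer lengths (bp).
#' @param copy_number integer copy numbers, each 1 or 2.
#' @param is_x logical; exactly one chromosome must be flagged as X.
#' @param is_mito logical; mitochondrial chromosomes are excluded from
#'   normalization medians, genome fractions and gene annotation.
#' @return A `data.frame` of class `karyotype` with one row per chromosome.
#' @examples
#' karyotype(c("I", "X"), c(15e6, 17e6), c(2, 1), is_x = c(FALSE, TRUE))
#' @export
karyotype <- function(chrom, length_bp, copy_number,
                      is_x = chrom == "X",
                      is_mito = rep(FALSE, length(chrom))) {
  chrom <- as.character(chrom)
  n <- length(chrom)
  if (n == 0L) stop_("karyotype needs at least one chromosome")
  if (anyDuplicated(chrom)) stop_("duplicated chromosome names")
  if (length(length_bp) != n || length(copy_number) != n ||
      length(is_x) != n || length(is_mito) != n) {
    stop_("all karyotype fields must have one entry per chromosome")
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop_("chromosome lengths must be positive")
  }
  if (!all(copy_number %in% c(1L, 2L))) {
    stop_("copy numbers must be 1 or 2")
  }
  if (sum(is_x) != 1L) stop_("exactly one chromosome must be flagged as X")
  if (is_mito[is_x]) stop_("the X chromosome cannot be mitochondrial")
  out <- data.frame(
    chrom = chrom,
    length_bp = as.numeric(length_bp),
    copy_number = as.integer(copy_number),
    is_x = as.logical(is_x),
    is_mito = as.logical(is_mito),
    stringsAsFactors = FALSE
  )
  class(out) <- c("karyotype", "data.frame")
  out
}

#' C. elegans-like karyotype
#'
#' Chromosome lengths approximating the WS235 assembly (I--V, X and the
#' 13.8 kb mitochondrial genome). With `sex = "XX"` the X fraction of the
#' copy-weighted genome is about 18\%; with `sex = "XO"` (single X) about
#' 10\%, matching the DNA-content predictions used when interpreting
#' territory volumes.
#'
#' @param sex `"XX"` (two X copies) or `"XO"` (one X copy).
#' @param include_mito include the mitochondrial chromosome.
#' @return A [karyotype] object.
#' @export
celegans_karyotype <- function(sex = c("XX", "XO"), include_mito = TRUE) {
  sex <- match.arg(sex)
  chrom <- c("I", "II", "III", "IV", "V", "X")
  len <- c(15072434, 15279421, 13783801, 17493829, 20924180, 17718942)
  copies <- c(2L, 2L, 2L, 2L, 2L, if (sex == "XX") 2L else 1L)
  mito <- rep(FALSE, 6L)
  if (include_mito) {
    chrom <- c(chrom, "MtDNA")
    len <- c(len, 13794)
    copies <- c(copies, 2L)
    mito <- c(mito, TRUE)
  }
  karyotype(chrom, len, copies, is_x = chrom == "X", is_mito = mito)
}

#' Copy-weighted genome fractions
#'
#' Fraction of the genome on each chromosome, weighting each chromosome by
#' its copy number (so a single male X contributes half the weight of an
#' autosome pair of the same length). Mitochondrial chromosomes are
#' excluded. This is the denominator of the ChIP read-fraction ratio.
#'
#' @param karyotype a [karyotype] object.
#' @param copy_weighted multiply lengths by copy numbers (default `TRUE`).
#' @return Named numeric vector of fractions summing to 1.
#' @export
genome_fraction <- function(karyotype, copy_weighted = TRUE) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype[!karyotype$is_mito, , drop = FALSE]
  w <- k$length_bp * if (copy_weighted) k$copy_number else 1
  stats::setNames(w / sum(w), k$chrom)
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("karyotype: %d chromosomes (%s mode), X = %s\n",
              nrow(x),
              if (x$copy_number[x$is_x] == 2L) "XX" else "XO",
              x$chrom[x$is_x]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
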