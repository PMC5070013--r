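#' Simulate ChIP and input read sets with planted enrichment islands
#'
#' Draws single-end read positions whose expected per-chromosome counts
#' follow copy_number x length x per-copy density, optionally modulated by
#' planted enrichment islands (contiguous intervals where the local
#' density is multiplied by `island_fold`). Input (whole-cell extract)
#' reads follow copy_number x length only, so the input track carries the
#' ploidy signal and none of the acetylation signal. This reproduces the
#' structure the ploidy-aware normalization and the read-fraction ratio
#' assume: under uniform per-copy density the expected ratio of X read
#' fraction to copy-weighted X genome fraction is exactly 1 for any
#' karyotype, and scaling the X per-copy density scales the ratio
#' accordingly.
#'
#' Islands are placed one per equal-width slot with uniform jitter inside
#' the slot interior, which guarantees a minimum edge-to-edge separation
#' larger than the default peak-merging gap.
#'
#' @param karyotype a [karyotype] object.
#' @param total_reads number of ChIP reads (> 0).
#' @param input_reads number of input reads.
#' @param density named per-copy baseline density per chromosome
#'   (relative units); unnamed scalar recycles to all chromosomes.
#' @param islands_per_mb planted island density per chromosome (named
#'   vector or scalar; 0 disables islands).
#' @param island_width_bp length-2 range; island widths are uniform in it.
#' @param island_fold density multiplier inside islands (> 1).
#' @param read_length_bp read length for the emitted intervals.
#' @param seed RNG seed.
#' @return list with `chip` and `input` (data.frames chrom/start/end,
#'   0-based half-open), `islands` (planted truth intervals) and `params`.
#' @export
gen_chip_reads <- function(karyotype,
                           total_reads = 1e6,
                           input_reads = total_reads,
                           density = 1,
                           islands_per_mb = 0,
                           island_width_bp = c(400, 1200),
                           island_fold = 8,
                           read_length_bp = 50,
                           seed = 1) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (total_reads <= 0) stop_("total_reads must be > 0")
  if (island_fold <= 1) stop_("island_fold must be > 1")
  chroms <- karyotype$chrom
  dens <- expand_by_chrom(density, chroms, "density")
  ipm <- expand_by_chrom(islands_per_mb, chroms, "islands_per_mb")
  if (any(dens < 0) || any(ipm < 0)) stop_("densities must be >= 0")
  if (all(dens * karyotype$length_bp * karyotype$copy_number == 0)) {
    stop_("zero total density: no chromosome can receive reads")
  }

  with_seed(seed, {
    # plant islands
    isl <- lapply(seq_along(chroms), function(ci) {
      len <- karyotype$length_bp[ci]
      n_isl <- as.integer(round(ipm[ci] * len / 1e6))
      if (n_isl < 1L || karyotype$is_mito[ci]) return(NULL)
      slot <- len / n_isl
      w <- round(stats::runif(n_isl, island_width_bp[1L], island_width_bp[2L]))
      margin <- pmin(600, pmax(0, (slot - w) / 2 * 0.5))
      start <- round((seq_len(n_isl) - 1L) * slot + margin +
                     stats::runif(n_isl) * pmax(0, slot - w - 2 * margin))
      data.frame(chrom = chroms[ci], start = start, end = start + w,
                 fold = island_fold, stringsAsFactors = FALSE)
    })
    isl <- do.call(rbind, isl)
    isl_bp <- stats::setNames(numeric(length(chroms)), chroms)
    if (!is.null(isl)) {
      agg <- tapply(isl$end - isl$start, isl$chrom, sum)
      isl_bp[names(agg)] <- agg
    }

    # expected per-chromosome weights: background + island excess
    w_chip <- karyotype$copy_number * dens *
      (karyotype$length_bp + isl_bp[chroms] * (island_fold - 1) * (isl_bp[chroms] > 0))
    w_input <- karyotype$copy_number * karyotype$length_bp

    chip <- sample_reads(karyotype, total_reads, w_chip, isl, isl_bp,
                         island_fold, read_length_bp)
    input <- sample_reads(karyotype, input_reads, w_input, NULL, NULL,
                          island_fold, read_length_bp)
    list(chip = chip, input = input,
         islands = isl %||% data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0), fold = numeric(0)),
         params = list(total_reads = total_reads, input_reads = input_reads,
                       density = dens, islands_per_mb = ipm,
                       island_width_bp = island_width_bp,
                       island_fold = island_fold,
                       read_length_bp = read_length_bp, seed = seed))
  })
}

expand_by_chrom <- function(x, chroms, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(chroms)), chroms))
  }
  out <- stats::setNames(numeric(length(chroms)), chroms)
  if (is.null(names(x)) || !all(names(x) %in% chroms)) {
    stop_(sprintf("%s must be a scalar or named by chromosome", what))
  }
  out[names(x)] <- as.numeric(x)
  if (length(x) < length(chroms) && what == "density") out[setdiff(chroms, names(x))] <- 1
  out
}

sample_reads <- function(karyotype, n_reads, weights, islands, isl_bp,
                         fold, read_len) {
  n_per <- as.vector(stats::rmultinom(1L, n_reads, weights))
  out <- vector("list", nrow(karyotype))
  for (ci in seq_len(nrow(karyotype))) {
    n_c <- n_per[ci]
    if (n_c == 0L) next
    chrom <- karyotype$chrom[ci]
    len <- karyotype$length_bp[ci]
    pos <- numeric(n_c)
    n_bg <- n_c
    if (!is.null(islands) && isl_bp[chrom] > 0) {
      # decompose density as uniform background + (fold-1) excess on islands
      p_extra <- isl_bp[chrom] * (fold - 1) / (len + isl_bp[chrom] * (fold - 1))
      n_extra <- stats::rbinom(1L, n_c, p_extra)
      n_bg <- n_c - n_extra
      if (n_extra > 0L) {
        isl_c <- islands[islands$chrom == chrom, , drop = FALSE]
        widths <- isl_c$end - isl_c$start
        pick <- sample.int(nrow(isl_c), n_extra, replace = TRUE,
                           prob = widths)
        pos[seq_len(n_extra)] <- isl_c$start[pick] +
          stats::runif(n_extra) * widths[pick]
      }
    }
    if (n_bg > 0L) {
      pos[(n_c - n_bg + 1L):n_c] <- stats::runif(n_bg) * len
    }
    start <- pmax(0, floor(pos - read_len / 2))
    start <- pmin(start, max(0, len - read_len))
    out[[ci]] <- data.frame(chrom = chrom, start = start,
                            end = start + read_len,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Solve the X per-copy density factor for a target read-fraction ratio
#'
#' Given a karyotype and a target ratio of (X read fraction) to
#' (copy-weighted X genome fraction), returns the X per-copy density
#' factor (relative to autosomal density 1) whose expected ratio equals
#' the target. Used by the packaged XX ChIP scenarios, where the X factor
#' is solved analytically so the planted expectation matches the reported
#' depletion.
#'
#' @param karyotype a [karyotype] object.
#' @param target_ratio desired expected ratio (e.g. 0.33 for the
#'   DCC-depleted hermaphrodite X).
#' @return scalar density factor for the X chromosome.
#' @export
solve_x_density_factor <- function(karyotype, target_ratio) {
  stopifnot(inherits(karyotype, "karyotype"), target_ratio > 0)
  k <- karyotype[!karyotype$is_mito, , drop = FALSE]
  wx <- sum(k$length_bp[k$is_x] * k$copy_number[k$is_x])
  wa <- sum(k$length_bp[!k$is_x] * k$copy_number[!k$is_x])
  gx <- wx / (wx + wa)
  p <- target_ratio * gx  # desired X read fraction
  if (p >= 1) stop_("target ratio unattainably high for this karyotype")
  (p * wa) / (wx * (1 - p))
}
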