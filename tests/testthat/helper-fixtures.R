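# Shared fixtures and independent oracles used across the suite.

tiny_karyotype <- function(sex = "XX", len_a = 2e6, len_x = 1e6) {
  karyotype(c("A1", "X"), c(len_a, len_x),
            c(2L, if (sex == "XX") 2L else 1L),
            is_x = c(FALSE, TRUE))
}

# coverage_track from a plain list of per-chromosome bin values
make_track <- function(values, bin_size = 50,
                       semantics = "input_subtracted",
                       chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(values, function(v) length(v) * bin_size, 0)
  }
  coverage_track(values, bin_size, semantics, chrom_lengths)
}

# Independent broad-peak oracle: expand the z track to bp resolution,
# then do a literal run-length scan on the bp boolean vector (merge
# sub-gap FALSE runs, drop short TRUE runs). Only for small tracks.
oracle_broad_peaks <- function(ztrack, z_min, merge_gap, min_len) {
  out <- lapply(names(ztrack$values), function(ch) {
    z <- ztrack$values[[ch]]
    len <- ztrack$chrom_lengths[[ch]]
    bp <- rep(z, each = ztrack$bin_size)[seq_len(len)] >= z_min
    r <- rle(bp)
    # fill gaps shorter than merge_gap that sit between two hot runs
    if (length(r$lengths) > 2L) {
      for (i in 2L:(length(r$values) - 1L)) {
        if (!r$values[i] && r$lengths[i] < merge_gap &&
            r$values[i - 1L] && r$values[i + 1L]) {
          r$values[i] <- TRUE
        }
      }
    }
    bp <- inverse.rle(r)
    r2 <- rle(bp)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths
    hot <- which(r2$values & r2$lengths >= min_len)
    if (length(hot) == 0L) return(NULL)
    data.frame(chrom = ch, start = starts[hot], end = ends[hot],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  }
  rownames(res) <- NULL
  res
}

# Brute-force exact one-sided Wilcoxon p-value by enumeration of all
# group assignments, using the Mann-Whitney count statistic computed
# from pairwise comparisons (a derivation independent of rank sums).
oracle_wilcox_exact <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U_obs <- U_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  Us <- apply(combos, 2L, U_of)
  eps <- 1e-9
  switch(alternative,
         greater = mean(Us >= U_obs - eps),
         less = mean(Us <= U_obs + eps),
         two.sided = min(1, 2 * min(mean(Us >= U_obs - eps),
                                    mean(Us <= U_obs + eps))))
}

# Exhaustive minimum-weight matching over all injective assignments of
# the smaller spot set into the larger one (<= 3 x 3 instances).
oracle_min_matching <- function(A, B) {
  swap <- nrow(A) > nrow(B)
  if (swap) { tmp <- A; A <- B; B <- tmp }
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  perms <- combinat_perms(m)
  best <- Inf; best_pairs <- NULL
  for (p in perms) {
    sel <- p[seq_len(n)]
    tot <- sum(vapply(seq_len(n), function(i) d(i, sel[i]), 0))
    if (tot < best) { best <- tot; best_pairs <- sel }
  }
  dists <- vapply(seq_len(n), function(i) d(i, best_pairs[i]), 0)
  list(total = best, distances = sort(dists))
}

combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

# Brute-force Otsu: sweep every candidate threshold (midpoints of the
# sorted unique values), maximizing between-class variance directly.
oracle_otsu_sweep <- function(x) {
  u <- sort(unique(x))
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(hi) - mean(lo))^2
  }, 0)
  cand[which.max(bcv)]
}

as_spots <- function(m) {
  stats::setNames(as.data.frame(m), c("x", "y", "z"))
}
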