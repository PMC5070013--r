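zt <- function(z, bin_size = 50, chrom = "X") {
  lens <- stats::setNames(length(z) * bin_size, chrom)
  vals <- stats::setNames(list(z), chrom)
  coverage_track(vals, bin_size, "zscore", lens)
}

test_that("peak caller trivial and hand-traced cases", {
  expect_equal(nrow(call_broad_peaks(zt(rep(0, 100)), z_min = 2.5)), 0L)
  # 10-bin run at z=5, a 1-bin gap, a 5-bin run; gap 50 bp < merge_gap
  z <- c(rep(0, 10), rep(5, 10), 0, rep(5, 5), rep(0, 20))
  pk <- call_broad_peaks(zt(z), z_min = 2.5, merge_gap = 500, min_len = 200)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 10 * 50)
  expect_equal(pk$end, 26 * 50)
  # same track, merge_gap smaller than the gap: two peaks, one dropped by min_len
  pk2 <- call_broad_peaks(zt(z), z_min = 2.5, merge_gap = 50, min_len = 200)
  expect_equal(nrow(pk2), 2L)
  pk3 <- call_broad_peaks(zt(z), z_min = 2.5, merge_gap = 50, min_len = 300)
  expect_equal(nrow(pk3), 1L)
  expect_error(call_broad_peaks(zt(z), z_min = 0), "> 0")
})

test_that("peak caller equals the bp-resolution run-length oracle", {
  set.seed(6)
  for (rep in 1:8) {
    nb <- sample(200:1000, 1)
    z <- rnorm(nb)
    hot <- sort(sample(nb, 25))
    z[hot] <- z[hot] + runif(25, 3, 8)
    track <- zt(z, bin_size = sample(c(50, 100), 1))
    params <- list(z_min = runif(1, 1.5, 3),
                   merge_gap = sample(c(100, 300, 500), 1),
                   min_len = sample(c(100, 200, 400), 1))
    got <- call_broad_peaks(track, params$z_min, params$merge_gap,
                            params$min_len)
    want <- oracle_broad_peaks(track, params$z_min, params$merge_gap,
                               params$min_len)
    expect_equal(nrow(got), nrow(want), label = sprintf("rep %d", rep))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("raising z_min never increases the count of plateau peaks", {
  # island-like signal: flat plateaus of varying height over sub-threshold
  # background; a plateau either survives a threshold whole or vanishes,
  # so the peak count is non-increasing in z_min
  set.seed(7)
  z <- rnorm(1000, 0, 0.3)
  starts <- seq(50, 950, by = 60)
  for (s in starts) z[s:(s + 8)] <- runif(1, 2, 8)
  track <- zt(z)
  counts <- vapply(seq(1, 8, by = 0.5), function(zm) {
    nrow(call_broad_peaks(track, z_min = zm, merge_gap = 200))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[length(counts)])
})

test_that("per-peak mean z is reported over the peak span", {
  z <- c(rep(0, 5), rep(4, 10), rep(0, 5))
  pk <- call_broad_peaks(zt(z), z_min = 2.5, merge_gap = 100, min_len = 100)
  expect_equal(pk$mean_z, 4)
})

test_that("read-fraction ratios are 1 under uniform per-copy density", {
  for (sex in c("XX", "XO")) {
    k <- celegans_karyotype(sex)
    sim <- gen_chip_reads(k, total_reads = 5e5, seed = 8)
    rr <- read_fraction_ratio(sim$chip, k)
    expect_true(all(abs(rr$ratio - 1) < 0.02), label = sex)
    expect_equal(sum(rr$read_fraction), 1)
    expect_equal(sum(rr$genome_fraction), 1)
  }
  expect_error(read_fraction_ratio(data.frame(chrom = character(0)),
                                   celegans_karyotype()), "empty")
})

test_that("input reads double when a chromosome's copy number doubles", {
  # same X length, copy 1 vs copy 2: expected X input count doubles
  k1 <- tiny_karyotype("XO", len_a = 4e6, len_x = 2e6)
  k2 <- tiny_karyotype("XX", len_a = 4e6, len_x = 2e6)
  n_x <- function(k) {
    sim <- gen_chip_reads(k, total_reads = 4e5, seed = 9)
    sum(sim$input$chrom == "X")
  }
  # copy-weighted expectations: 2e6/10e6 vs 4e6/12e6 of 4e5 reads
  expect_equal(n_x(k1), 4e5 * 2e6 / 1e7, tolerance = 0.03)
  expect_equal(n_x(k2), 4e5 * 4e6 / 1.2e7, tolerance = 0.03)
})

test_that("planted island read excess follows the island model", {
  k <- tiny_karyotype("XX", len_a = 5e6, len_x = 5e6)
  sim <- gen_chip_reads(k, total_reads = 4e5, islands_per_mb = 10,
                        island_fold = 8, seed = 10)
  isl <- sim$islands
  expect_gt(nrow(isl), 0)
  # min island separation exceeds the default merge gap
  for (ch in unique(isl$chrom)) {
    ic <- isl[isl$chrom == ch, ]
    ic <- ic[order(ic$start), ]
    if (nrow(ic) > 1) {
      expect_gt(min(ic$start[-1] - ic$end[-nrow(ic)]), 500)
    }
  }
  # reads inside islands are ~fold x denser than background
  mid <- floor((sim$chip$start + sim$chip$end) / 2)
  isl_x <- isl[isl$chrom == "X", ]
  in_isl <- vapply(mid[sim$chip$chrom == "X"], function(p) {
    any(p >= isl_x$start & p < isl_x$end)
  }, TRUE)
  isl_bp <- sum(isl_x$end - isl_x$start)
  dens_ratio <- (sum(in_isl) / isl_bp) / (sum(!in_isl) / (5e6 - isl_bp))
  expect_equal(dens_ratio, 8, tolerance = 0.1)
})

test_that("peak density covers trivial and pooled cases", {
  k <- karyotype(c("A1", "X"), c(17e6, 17e6), c(2, 2), is_x = c(FALSE, TRUE))
  pk <- data.frame(chrom = rep("A1", 17), start = 1:17 * 1e5)
  pk$end <- pk$start + 100
  d <- peak_density(pk, k)
  expect_equal(d$per_chromosome$peaks_per_mb[1], 1)
  expect_equal(d$autosome_density, 1)
  expect_equal(d$x_density, 0)
  empty <- peak_density(data.frame(chrom = character(0)), k)
  expect_true(all(empty$per_chromosome$peaks_per_mb == 0))
})
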