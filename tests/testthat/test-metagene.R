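# A small two-chromosome annotation with a z track built per test.
meta_setup <- function(seed = 13, genes_per_mb = 20) {
  k <- tiny_karyotype("XX")
  ann <- gen_genome_annotation(k, genes_per_mb = genes_per_mb, seed = seed)
  lens <- stats::setNames(k$length_bp, k$chrom)
  list(k = k, ann = ann, lens = lens)
}

const_track <- function(lens, value, bin_size = 200) {
  vals <- lapply(lens, function(L) rep(value, ceiling(L / bin_size)))
  coverage_track(vals, bin_size, "zscore", lens)
}

test_that("a constant track gives a flat profile at that constant", {
  s <- meta_setup()
  tr <- const_track(s$lens, 0.7)
  prof <- metagene_profile(tr, s$ann$genes, body_bins = 40, flank_bins = 10)
  expect_setequal(unique(prof$stratum), c("X", "autosome"))
  expect_true(all(abs(prof$z_mean - 0.7) < 1e-9))
  expect_equal(sum(prof$stratum == "X"), 60)  # 10 + 40 + 10 positions
})

test_that("metagene is linear in the track", {
  s <- meta_setup()
  set.seed(1)
  v1 <- lapply(s$lens, function(L) rnorm(ceiling(L / 200)))
  v2 <- lapply(s$lens, function(L) rnorm(ceiling(L / 200)))
  t1 <- coverage_track(v1, 200, "zscore", s$lens)
  t2 <- coverage_track(v2, 200, "zscore", s$lens)
  t12 <- coverage_track(Map(`+`, v1, v2), 200, "zscore", s$lens)
  p1 <- metagene_profile(t1, s$ann$genes, body_bins = 30, flank_bins = 5)
  p2 <- metagene_profile(t2, s$ann$genes, body_bins = 30, flank_bins = 5)
  p12 <- metagene_profile(t12, s$ann$genes, body_bins = 30, flank_bins = 5)
  expect_equal(p12$z_mean, p1$z_mean + p2$z_mean, tolerance = 1e-9)
})

test_that("mirroring the genome and flipping strands leaves profiles unchanged", {
  s <- meta_setup(genes_per_mb = 10)
  set.seed(2)
  bs <- 200  # chromosome lengths are multiples of the bin size
  vals <- lapply(s$lens, function(L) rnorm(L / bs))
  tr <- coverage_track(vals, bs, "zscore", s$lens)
  g <- s$ann$genes
  prof <- metagene_profile(tr, g, body_bins = 30, flank_bins = 5)
  # mirror: position x -> len - x, strand flipped, bins reversed
  g2 <- g
  g2$start <- s$lens[g$chrom] - g$end
  g2$end <- s$lens[g$chrom] - g$start
  g2$strand <- ifelse(g$strand == "+", "-", "+")
  tr2 <- coverage_track(lapply(vals, rev), bs, "zscore", s$lens)
  prof2 <- metagene_profile(tr2, g2, body_bins = 30, flank_bins = 5)
  expect_equal(prof$z_mean, prof2$z_mean, tolerance = 1e-9)
})

test_that("a planted TSS-proximal bump peaks in the first quarter of the axis", {
  s <- meta_setup(genes_per_mb = 15)
  bs <- 100
  vals <- lapply(s$lens, function(L) rep(0, ceiling(L / bs)))
  g <- s$ann$genes
  for (i in seq_len(nrow(g))) {   # enrich [TSS, TSS + 400) on each gene
    tss_bin <- g$tss[i] %/% bs + 1
    bins <- tss_bin + if (g$strand[i] == "+") 0:3 else -(3:0)
    bins <- bins[bins >= 1 & bins <= length(vals[[g$chrom[i]]])]
    vals[[g$chrom[i]]][bins] <- 5
  }
  tr <- coverage_track(vals, bs, "zscore", s$lens)
  prof <- metagene_profile(tr, g, body_bins = 60, flank_bins = 12)
  for (st in unique(prof$stratum)) {
    p <- prof[prof$stratum == st, ]
    expect_lt(which.max(p$z_mean), nrow(p) / 4)
  }
})

test_that("an X depletion factor keeps the X profile below the autosomal one", {
  s <- meta_setup()
  set.seed(3)
  vals <- lapply(names(s$lens), function(ch) {
    base <- if (ch == "X") 0.3 else 1.0
    base + rnorm(ceiling(s$lens[[ch]] / 200), 0, 0.02)
  })
  names(vals) <- names(s$lens)
  tr <- coverage_track(vals, 200, "zscore", s$lens)
  prof <- metagene_profile(tr, s$ann$genes, body_bins = 40, flank_bins = 8)
  px <- prof$z_mean[prof$stratum == "X"]
  pa <- prof$z_mean[prof$stratum == "autosome"]
  expect_true(all(px < pa))
})

test_that("expression quartiles split evenly and order with planted signal", {
  s <- meta_setup(genes_per_mb = 30)
  g <- s$ann$genes
  set.seed(4)
  expr <- data.frame(gene_id = g$gene_id,
                     mean_rpkm = exp(rnorm(nrow(g), log(20), 1)))
  # plant acetylation on each gene body proportional to log expression,
  # saturating for the top half of genes
  bs <- 100
  vals <- lapply(s$lens, function(L) rep(0, ceiling(L / bs)))
  med <- median(expr$mean_rpkm)  # signal saturates for the top half
  for (i in seq_len(nrow(g))) {
    lev <- min(log(expr$mean_rpkm[i]), log(med))
    b1 <- g$start[i] %/% bs + 1
    b2 <- g$end[i] %/% bs
    vals[[g$chrom[i]]][b1:b2] <- lev
  }
  tr <- coverage_track(vals, bs, "zscore", s$lens)
  prof <- quartile_profiles(tr, g, expr, by_class = FALSE,
                            body_bins = 30, flank_bins = 5)
  means <- tapply(prof$z_mean[prof$region == "body"],
                  prof$stratum[prof$region == "body"], mean)
  expect_true(means[["Q1"]] < means[["Q2"]])
  expect_true(means[["Q2"]] < means[["Q3"]])
  # saturation: top two quartiles nearly identical
  expect_equal(means[["Q3"]], means[["Q4"]], tolerance = 0.1)
  # constant expression: quartile sizes n/4 +/- 1
  expr2 <- data.frame(gene_id = g$gene_id, mean_rpkm = 5)
  prof2 <- quartile_profiles(tr, g, expr2, by_class = FALSE,
                             body_bins = 10, flank_bins = 2)
  ns <- unique(prof2[, c("stratum", "n_genes")])
  expect_equal(nrow(ns), 4L)
  expect_true(all(abs(ns$n_genes - nrow(g) / 4) <= 1))
  expect_error(quartile_profiles(tr, g[1:3, ], expr, by_class = FALSE),
               "at least 4")
})

test_that("tss_upstream_score averages the strand-oriented window", {
  s <- meta_setup(genes_per_mb = 10)
  tr <- const_track(s$lens, 1.5)
  sc <- tss_upstream_score(tr, s$ann$genes)
  expect_true(all(abs(sc$score - 1.5) < 1e-9))
  expect_false(any(sc$clipped))
  # a gene hugging the chromosome start gets a clipped window
  g <- s$ann$genes[1, ]
  g$start <- 100; g$end <- 2000; g$tss <- 100; g$strand <- "+"
  sc2 <- tss_upstream_score(tr, g)
  expect_true(sc2$clipped)
  expect_equal(sc2$score, 1.5, tolerance = 1e-9)
  # planted dependence of the upstream window on expression is recovered
  set.seed(5)
  g3 <- s$ann$genes
  g3 <- g3[g3$strand == "+", ]
  expr <- exp(rnorm(nrow(g3), log(10), 1))
  bs <- 100
  vals <- lapply(s$lens, function(L) rep(0, ceiling(L / bs)))
  for (i in seq_len(nrow(g3))) {
    b <- (g3$tss[i] - 500) %/% bs + seq_len(5)
    vals[[g3$chrom[i]]][b] <- 0.5 + 0.8 * log(expr[i]) + rnorm(1, 0, 0.2)
  }
  tr3 <- coverage_track(vals, bs, "zscore", s$lens)
  sc3 <- tss_upstream_score(tr3, g3)
  expect_gt(cor(sc3$score, expr, method = "spearman"), 0.5)
})

test_that("quartile boundaries send ties to the lower quartile", {
  s <- meta_setup(genes_per_mb = 10)
  tr <- const_track(s$lens, 1)
  g <- s$ann$genes[1:8, ]
  expr <- data.frame(gene_id = g$gene_id,
                     mean_rpkm = c(1, 1, 2, 2, 3, 3, 4, 4))
  prof <- quartile_profiles(tr, g, expr, by_class = FALSE,
                            body_bins = 5, flank_bins = 1)
  ns <- unique(prof[, c("stratum", "n_genes")])
  expect_equal(sum(ns$n_genes), 8)
})
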