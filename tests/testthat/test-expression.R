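fake_table <- function(chrom, mean_rpkm, norm_mean = mean_rpkm,
                       ids = NULL) {
  n <- length(mean_rpkm)
  out <- data.frame(
    gene_id = ids %||% sprintf("g%03d", seq_len(n)),
    chrom = chrom, exonic_bp = 1000,
    mean_count = norm_mean, norm_mean = norm_mean, mean_rpkm = mean_rpkm,
    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RPKM follows the formula and its invariances", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "X",
                      exonic_bp = c(1000, 2000))
  counts <- matrix(c(100, 0), 2, 1, dimnames = list(genes$gene_id, "r1"))
  tab <- compute_rpkm(counts, genes, library_sizes = 1e6)
  expect_equal(tab$mean_rpkm, c(100, 0))
  # doubling every count and the library size leaves RPKM unchanged
  tab2 <- compute_rpkm(counts * 2, genes, library_sizes = 2e6)
  expect_equal(tab2$mean_rpkm, tab$mean_rpkm)
  expect_error(compute_rpkm(counts, genes, library_sizes = 0), "> 0")
  genes$exonic_bp[1] <- 0
  expect_error(compute_rpkm(counts, genes), "> 0")
})

test_that("median X:A ratio on toy and null tables", {
  toy <- fake_table(rep(c("X", "A1"), each = 3), c(2, 4, 6, 4, 8, 12))
  expect_equal(median_xa_ratio(toy, min_rpkm = 0)$ratio, 0.5)
  null <- fake_table(rep(c("X", "A1"), each = 50),
                     rep(c(5, 10, 20, 40, 80), 20))
  expect_equal(median_xa_ratio(null, min_rpkm = 1)$ratio, 1)
  # RPKM > min_rpkm filter is applied before the medians
  filt <- fake_table(rep(c("X", "A1"), each = 3), c(0.5, 4, 6, 0.5, 4, 6))
  res <- median_xa_ratio(filt, min_rpkm = 1)
  expect_equal(res$n_x, 2)
  expect_equal(res$ratio, 1)
  expect_error(median_xa_ratio(fake_table("A1", c(2, 3))), "X-linked")
  # scale invariance
  sc <- fake_table(rep(c("X", "A1"), each = 3), c(2, 4, 6, 4, 8, 12) * 37)
  expect_equal(median_xa_ratio(sc, min_rpkm = 0)$ratio, 0.5)
})

test_that("contrast_log2 is zero on identical inputs and antisymmetric", {
  t1 <- fake_table(rep(c("X", "A1"), 10), exp(rnorm(20, 3)))
  expect_true(all(contrast_log2(t1, t1)$log2_ratio == 0))
  t2 <- fake_table(rep(c("X", "A1"), 10), exp(rnorm(20, 3)))
  ab <- contrast_log2(t1, t2, pseudocount = 1)
  ba <- contrast_log2(t2, t1, pseudocount = 1)
  expect_equal(ab$log2_ratio, -ba$log2_ratio, tolerance = 1e-12)
})

test_that("shift test finds planted directional X effects", {
  set.seed(14)
  n <- 300
  ctr <- data.frame(
    gene_id = sprintf("g%04d", 1:(2 * n)),
    chrom = rep(c("X", "A1"), each = n),
    log2_ratio = c(rnorm(n, 0.3, 0.3), rnorm(n, 0, 0.3)))
  res <- chromosome_shift_test(ctr, direction = "greater")
  expect_lt(res$p_value[res$comparison == "X_vs_autosomes"], 1e-6)
  # identical distributions: p near 0.5
  ctr2 <- ctr
  ctr2$log2_ratio <- rep(rnorm(n, 0, 0.3), 2)
  res2 <- chromosome_shift_test(ctr2, direction = "greater")
  expect_gt(res2$p_value[1], 0.2)
  expect_lt(res2$p_value[1], 0.8)
  expect_error(chromosome_shift_test(ctr[1:3, ], "greater"), "fewer than")
})

test_that("shift test p-values match the exact oracle at tiny n", {
  set.seed(15)
  for (rep in 1:4) {
    ctr <- data.frame(
      gene_id = sprintf("g%02d", 1:12),
      chrom = rep(c("X", "A1"), each = 6),
      log2_ratio = round(rnorm(12, 0, 1), 2))
    res <- chromosome_shift_test(ctr, direction = "greater")
    want <- oracle_wilcox_exact(ctr$log2_ratio[1:6], ctr$log2_ratio[7:12],
                                "greater")
    expect_equal(res$p_value[res$comparison == "X_vs_autosomes"], want,
                 tolerance = 1e-9)
  }
})

test_that("quadrant classification places genes by thresholded sign pattern", {
  ca <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   chrom = c("X", "X", "A1", "X"),
                   log2_ratio = c(0.5, 0.05, 0.3, -0.4))
  cb <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   chrom = c("X", "X", "A1", "X"),
                   log2_ratio = c(-0.5, -0.5, 0.2, -0.15))
  qt <- quadrant_classify(ca, cb, threshold = 0.1)
  get <- function(cl, q) qt$n[qt$class == cl & qt$quadrant == q]
  expect_equal(get("X", "up_down"), 1)       # g1
  expect_equal(get("X", "unclassified"), 1)  # g2 below threshold on A
  expect_equal(get("X", "down_down"), 1)     # g4
  expect_equal(get("autosome", "up_up"), 1)  # g3
  # percentages per class sum to 100
  for (cl in c("X", "autosome")) {
    expect_equal(sum(qt$percent[qt$class == cl]), 100)
  }
  # threshold 0 classifies every non-zero gene
  qt0 <- quadrant_classify(ca, cb, threshold = 0)
  expect_equal(qt0$n[qt0$quadrant == "unclassified"], c(0, 0))
})

test_that("top-percent sets rank deterministically and track correlation", {
  set.seed(16)
  n <- 100
  ref <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "X",
                    log2_ratio = rnorm(n))
  comp <- ref
  comp$log2_ratio <- -0.8 * ref$log2_ratio + rnorm(n, 0, 0.2)
  res <- top_percent_sets(ref, comp, pcts = c(5, 10, 15))
  expect_length(res$sets$top5, 5L)
  expect_setequal(res$sets$top5,
                  ref$gene_id[order(-ref$log2_ratio)][1:5])
  expect_true(all(res$sets$top5 %in% res$sets$top10))
  # planted anti-correlation: top-5% companion median larger in magnitude
  s <- res$summary
  expect_gte(abs(s$companion_median[s$set == "top5pct"]),
             abs(s$companion_median[s$set == "all_x"]))
  # all-equal reference ratios: set determined by gene id, stable
  ref2 <- ref; ref2$log2_ratio <- 1
  r1 <- top_percent_sets(ref2, comp)$sets$top10
  r2 <- top_percent_sets(ref2, comp)$sets$top10
  expect_identical(r1, r2)
  expect_identical(r1, sort(ref2$gene_id)[1:10])
  expect_error(top_percent_sets(ref[1:10, ], comp), ">= 20")
})

test_that("expression generator plants recoverable medians and effects", {
  k <- tiny_karyotype("XX", len_a = 8e6, len_x = 4e6)
  ann <- gen_genome_annotation(k, genes_per_mb = 120, seed = 17)
  sim <- gen_expression_counts(
    ann, conditions = list(control = list(),
                           mut = list(x_log2 = list(median = 0.4, sd = 0.2))),
    x_ratio = 0.9, seed = 18)
  # determinism
  sim2 <- gen_expression_counts(
    ann, conditions = list(control = list(),
                           mut = list(x_log2 = list(median = 0.4, sd = 0.2))),
    x_ratio = 0.9, seed = 18)
  expect_identical(sim$counts, sim2$counts)
  # truth medians match the request (truth table, not pipeline output)
  on_x <- sim$truth$chrom == "X"
  expect_equal(median(sim$truth$log2_mut[on_x]), 0.4, tolerance = 0.03)
  expect_equal(median(sim$truth$baseline[on_x]) /
                 median(sim$truth$baseline[!on_x]), 0.9, tolerance = 0.05)
  # null: X:A ratio of 1 passes through the pipeline
  simn <- gen_expression_counts(ann, x_ratio = 1, seed = 19)
  tab <- compute_rpkm(simn$counts$control, simn$genes, simn$library_sizes)
  expect_equal(median_xa_ratio(tab)$ratio, 1, tolerance = 0.05)
  expect_error(gen_expression_counts(ann, dispersion = -1), ">= 0")
})

test_that("joint quadrant mode plants the requested X category fractions", {
  k <- tiny_karyotype("XX", len_a = 6e6, len_x = 6e6)
  ann <- gen_genome_annotation(k, genes_per_mb = 150, seed = 20)
  qp <- c(up_up = 0.05, up_down = 0.3, down_up = 0.05, down_down = 0.1)
  sim <- gen_expression_counts(
    ann, conditions = list(control = list(), a = list(), b = list()),
    joint_x = list(conditions = c("a", "b"), quadrant_probs = qp),
    dispersion = 0.005, seed = 21)
  frac <- mean(sim$quadrant_truth$category == "up_down")
  expect_equal(frac, 0.3, tolerance = 0.1)
  # planted signs are consistent with the category
  up_down <- sim$quadrant_truth$gene_id[sim$quadrant_truth$category == "up_down"]
  tr <- sim$truth[match(up_down, sim$truth$gene_id), ]
  expect_true(all(tr$log2_a > 0 & tr$log2_b < 0))
})
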