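test_that("students_t matches the hand-computed pooled-variance statistic", {
  res <- students_t(c(1, 2, 3), c(2, 3, 4))
  # pooled sd = 1, se = sqrt(2/3), t = -1/sqrt(2/3) = -1.224745
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(res$df, 4L)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("students_t agrees with the textbook computation on random data", {
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(5 + s, 1); b <- rnorm(12 - s, 1.4, 2)
    res <- students_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("students_t degenerate variance cases follow the limit", {
  expect_equal(students_t(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(students_t(c(2, 2, 2), c(3, 3))$p_value, 0)
  expect_equal(students_t(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  expect_error(students_t(1, c(1, 2)), "n >= 2")
})

test_that("exact Wilcoxon matches wilcox.test and brute-force enumeration", {
  set.seed(7)
  for (rep in 1:6) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- round(rnorm(n1, 0.3), 2); y <- round(rnorm(n2), 2)
    for (alt in c("greater", "less", "two.sided")) {
      mine <- wilcoxon_rank_sum(x, y, alternative = alt)
      expect_equal(mine$p_value, oracle_wilcox_exact(x, y, alt),
                   tolerance = 1e-9,
                   label = sprintf("rep %d alt %s", rep, alt))
      if (!any(duplicated(c(x, y)))) {
        ref <- wilcox.test(x, y, alternative = alt, exact = TRUE)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
        expect_equal(mine$statistic, unname(ref$statistic))
      }
    }
  }
})

test_that("exact Wilcoxon handles ties by mid-rank enumeration", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  for (alt in c("greater", "less", "two.sided")) {
    expect_equal(wilcoxon_rank_sum(x, y, alternative = alt)$p_value,
                 oracle_wilcox_exact(x, y, alt), tolerance = 1e-9)
  }
})

test_that("normal-approximation Wilcoxon matches the corrected reference", {
  set.seed(11)
  x <- rnorm(30, 0.5); y <- rnorm(45)
  for (alt in c("greater", "less", "two.sided")) {
    mine <- wilcoxon_rank_sum(x, y, alternative = alt)
    ref <- wilcox.test(x, y, alternative = alt, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  # with heavy ties, the tie-corrected variance is used
  xt <- rep(1:4, each = 5); yt <- rep(2:5, each = 5)
  ref <- wilcox.test(xt, yt, alternative = "less", exact = FALSE)
  expect_equal(wilcoxon_rank_sum(xt, yt, alternative = "less")$p_value,
               ref$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon null and degenerate behavior", {
  set.seed(2)
  v <- rnorm(40)
  res <- wilcoxon_rank_sum(v, v, alternative = "greater")
  expect_equal(res$p_value, 0.5, tolerance = 0.05)
  expect_warning(res2 <- wilcoxon_rank_sum(rep(1, 10), rep(1, 12)),
                 "tied")
  expect_equal(res2$p_value, 0.5)
})

test_that("a planted stochastic shift is detected in >=95% of runs", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    x <- rnorm(40, 0.8); y <- rnorm(40)
    if (wilcoxon_rank_sum(x, y, "greater")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("chi-square matches chisq.test without continuity correction", {
  expect_equal(chisq_proportions(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chisq_proportions(matrix(c(30, 15, 30, 15), 2))$p_value, 1)
  set.seed(3)
  for (rep in 1:4) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    mine <- chisq_proportions(tab)
    ref <- chisq.test(tab, correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chisq_proportions(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("the survival comparison is overwhelmingly significant", {
  surv <- c(round(0.98 * 2090), round(0.54 * 1071))
  tab <- cbind(surv, c(2090, 1071) - surv)
  res <- chisq_proportions(tab)
  expect_lt(res$p_value, 0.001)
  expect_equal(unname(res$proportions), c(0.98, 0.54), tolerance = 0.001)
})
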