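#' Unpaired two-sample Student's t-test
#'
#' Classical equal-variance (pooled) two-sample t statistic with a
#' two-sided p-value, the test used for all territory-volume and probe
#' distance comparisons. Degenerate zero-variance inputs are resolved by
#' the limit of the statistic: equal means give p = 1, unequal means
#' p = 0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return A `test_result`: statistic, df, p_value, method, alternative, n.
#' @export
students_t <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_("each group needs n >= 2")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    stat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  test_result(statistic = stat, p_value = p, df = df,
              method = "Two-sample Student's t-test (pooled variance)",
              alternative = "two.sided", n = c(n1, n2))
}

#' One- or two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test of a location shift between two samples. For groups of
#' at most `exact_max` observations each, the p-value is computed by
#' exact enumeration of all rank assignments (which handles ties
#' exactly); otherwise the normal approximation with tie correction and
#' continuity correction is used. This is the shift test applied to
#' per-chromosome log2 expression-ratio distributions.
#'
#' If every pooled value is tied the shift is undefined; p = 0.5 is
#' returned with a warning.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x shifted up) or
#'   `"less"`.
#' @param exact_max per-group size at or below which exact enumeration is
#'   used (default 8).
#' @return A `test_result` with the rank-sum statistic W (sum of ranks of
#'   `x` minus its minimum, i.e. the Mann-Whitney U).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  method <- "Wilcoxon rank-sum test"
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; shift undefined",
            call. = FALSE)
    return(test_result(statistic = U, p_value = 0.5,
                       method = paste(method, "(degenerate)"),
                       alternative = alternative, n = c(n1, n2)))
  }
  if (max(n1, n2) <= exact_max) {
    # exact permutation distribution of W over all group assignments
    combos <- utils::combn(n1 + n2, n1)
    Wperm <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p_ge <- mean(Wperm >= W - eps)
    p_le <- mean(Wperm <= W + eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- paste(method, "(exact enumeration)")
  } else {
    N <- n1 + n2
    mu <- n1 * (N + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      warning("zero rank variance; shift undefined", call. = FALSE)
      return(test_result(statistic = U, p_value = 0.5,
                         method = paste(method, "(degenerate)"),
                         alternative = alternative, n = c(n1, n2)))
    }
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((W - mu + 0.5) / sigma)
    p <- switch(alternative,
                greater = p_greater,
                less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
    method <- paste(method, "(normal approximation, tie + continuity corrected)")
  }
  test_result(statistic = U, p_value = p, method = method,
              alternative = alternative, n = c(n1, n2))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without Yates continuity correction, df = 1, plus
#' the two observed row proportions (first column over row total). Used
#' for the progeny survival and sex-ratio comparisons.
#'
#' @param tab 2x2 matrix of counts (rows = groups, columns = outcomes).
#' @return A `test_result` with `proportions`.
#' @export
chisq_proportions <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_("need a 2x2 count table")
  if (any(tab < 0)) stop_("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop_("zero row/column margin")
  expected <- outer(rs, cs) / n
  if (any(expected <= 0)) stop_("all cell expectations must be > 0")
  stat <- sum((tab - expected)^2 / expected)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  res <- test_result(statistic = stat, p_value = p, df = 1L,
                     method = "Pearson chi-square (no continuity correction)",
                     alternative = "two.sided", n = rs)
  res$proportions <- tab[, 1L] / rs
  res
}

test_result <- function(statistic, p_value, method, alternative, n,
                        df = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method,
                 alternative = alternative, n = unname(n)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g%s, p = %.4g (%s), n = %s\n",
              x$method, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}
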