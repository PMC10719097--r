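# Cohort statistics: extrapolation arithmetic, summary-based Welch test,
# exact rank tests against enumeration oracles, sample size and qPCR.

test_that("the abnormality extrapolation reproduces its boundary behavior", {
  expect_equal(extrapolate_abnormality_rate(
    cohort_counts(879, 866, 33, 94)), 67.8)
  # no hidden abnormality: plain karyotype rate
  expect_equal(extrapolate_abnormality_rate(cohort_counts(879, 866, 0, 94)),
               round(100 * 879 / 1745, 1))
  # everything abnormal by karyotype
  expect_equal(extrapolate_abnormality_rate(cohort_counts(100, 0, 5, 10)),
               100)
  # monotone in AH and bounded by the karyotype-only and all-normal rates
  prev <- -Inf
  for (ah in seq(0, 94, by = 7)) {
    r <- extrapolate_abnormality_rate(cohort_counts(879, 866, ah, 94))
    expect_gte(r, prev)
    expect_gte(r, round(100 * 879 / 1745, 1))
    expect_lte(r, 100)
    prev <- r
  }
  expect_error(cohort_counts(10, 5, 3, 4, TK = 16), "TK")
  expect_error(cohort_counts(10, 5, 6, 4), "AH")
})

test_that("Welch's t from summaries matches t.test on matching raw data", {
  # construct raw samples with exactly the requested mean/sd
  mk <- function(m, s, n) {
    x <- scale(rnorm(n))[, 1]
    m + s * x
  }
  set.seed(7)
  for (i in 1:5) {
    a <- mk(runif(1, 0, 10), runif(1, 0.5, 3), sample(10:60, 1))
    b <- mk(runif(1, 0, 10), runif(1, 0.5, 3), sample(10:60, 1))
    ours <- welch_t(summary_stats(mean(a), sd(a), length(a)),
                    summary_stats(mean(b), sd(b), length(b)))
    ref <- t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  ident <- welch_t(summary_stats(5, 1, 20), summary_stats(5, 1, 20))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  far <- welch_t(summary_stats(10, 1, 50), summary_stats(20, 1, 50))
  expect_lt(far$p, 1e-10)
  # maternal-age comparison from published group summaries: the summary
  # computation can only be checked to order of magnitude (the original p
  # came from raw ages)
  age <- welch_t(summary_stats(29.0, 6.4, 879), summary_stats(27.8, 5.9, 866))
  expect_lt(age$p, 1e-3)
  expect_error(summary_stats(1, 1, 1), "n must")
})

test_that("the signed-rank test matches exact enumeration at small n", {
  # all-positive differences at n = 5: p = 2/32
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p, 0.0625)
  # antisymmetric pairs: p = 1
  expect_equal(wilcoxon_signed_rank(c(2, -2, 5, -5, 7, -7, 9, -9))$p, 1)
  # a single pair: exact enumeration gives p = 1
  expect_equal(wilcoxon_signed_rank(1.5)$p, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    d <- round(rnorm(n, sd = 4), 2)
    d <- d[d != 0]
    if (length(d) == 0 || any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p, wsr_enum_p(d),
                 tolerance = 1e-9, info = paste(d, collapse = ","))
  }
})

test_that("the Mann-Whitney test matches exact enumeration at small n", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mann_whitney_u(1:4, 1:4)$p, 1)   # identical samples
  # rank statistic: invariant under a common monotone transform
  x <- c(0.3, 1.7, 4.2, 9.1); y <- c(0.9, 2.4, 6.6)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(exp(x), exp(y))$p)
  set.seed(13)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny), 3)
    if (any(duplicated(c(x, y)))) next
    expect_equal(mann_whitney_u(x, y)$p, mwu_enum_p(x, y),
                 tolerance = 1e-9)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 8, 8), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(1, 11, 9, 3), 2)),
               fisher_enum_p(matrix(c(1, 11, 9, 3), 2)), tolerance = 1e-9)
  set.seed(17)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_enum_p(tab),
                 tolerance = 1e-8)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("the paired-Wilcoxon sample size behaves monotonically", {
  base <- paired_wilcoxon_sample_size(15, 30, 30, 0.5)
  expect_equal(base$n, 35)
  expect_gte(base$achieved_power, 0.80)
  # doubling the detectable difference strictly decreases n
  expect_lt(paired_wilcoxon_sample_size(30, 30, 30, 0.5)$n, base$n)
  # higher correlation shrinks the paired sd and with it n
  ns <- vapply(c(0.1, 0.5, 0.9), function(r)
    paired_wilcoxon_sample_size(15, 30, 30, r)$n, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # more demanded power requires more pairs
  expect_gt(paired_wilcoxon_sample_size(15, 30, 30, 0.5, power = 0.95)$n,
            base$n)
  expect_error(paired_wilcoxon_sample_size(15, 30, 30, 1.0), "rho")
})

test_that("qPCR fold-change arithmetic and interpretation bands", {
  expect_equal(qpcr_fold_change(20, 20, -3.32, 0)$fold_change, 1)
  # four copies against a triploid three-copy reference: ~1.33
  slope <- -3.3219
  fc <- qpcr_fold_change(20 + slope * log10(4 / 3), 20, slope, 0)
  expect_equal(round(fc$fold_change, 2), 1.33)
  expect_identical(classify_fold_change(1.5), "duplication")
  expect_identical(classify_fold_change(0.5), "deletion")
  expect_identical(classify_fold_change(1.0), "two_copies")
  expect_identical(classify_fold_change(2.5), "indeterminate")
  expect_error(qpcr_fold_change(20, 19, 0, 0), "slope")
})
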