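# Cohort-level statistics: abnormality-rate extrapolation, group
# comparisons (Welch t, Wilcoxon signed-rank, Mann-Whitney U, Fisher),
# sample-size calculation for the paired Wilcoxon test, and qPCR
# fold-change arithmetic.

#' Cohort count container
#'
#' @param AK abnormal cases by conventional karyotyping.
#' @param NK normal cases by conventional karyotyping.
#' @param AH abnormal cases by genome haplarithmisis.
#' @param TH total cases analyzed by haplarithmisis.
#' @param TK total karyotyped cases; must equal `AK + NK`.
#' @return list of class `"cohort_counts"`.
#' @export
cohort_counts <- function(AK, NK, AH, TH, TK = AK + NK) {
  v <- c(AK = AK, NK = NK, AH = AH, TH = TH, TK = TK)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers")
  if (AK + NK != TK) stop("AK + NK must equal TK")
  if (AH > TH) stop("AH cannot exceed TH")
  structure(as.list(v), class = "cohort_counts")
}

#' Extrapolated abnormality prevalence
#'
#' Applies the extrapolation `((AK + NK * AH / TH) * 100) / TK`: the
#' karyotypically abnormal cases plus the expected number of haplarithmisis
#' -detectable aberrations among the karyotypically normal ones, as a
#' percentage of all karyotyped cases.  Reported to one decimal.
#'
#' @param counts a [cohort_counts()].
#' @return percentage, rounded to one decimal.
#' @export
extrapolate_abnormality_rate <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (counts$TH == 0 || counts$TK == 0) stop("TH and TK must be positive")
  round(((counts$AK + counts$NK * counts$AH / counts$TH) * 100) / counts$TK,
        1)
}

#' Group summary statistics
#'
#' @param mean,sd,n group mean, standard deviation and size (`n >= 2`,
#'   `sd >= 0`).
#' @return list of class `"summary_stats"`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (n < 2) stop("n must be at least 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

#' Two-sided Welch's t-test from summary statistics
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, computed
#' from group means, standard deviations and sizes (published tables rarely
#' provide raw data).
#'
#' @param a,b [summary_stats()] for the two groups.
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- if (va + vb == 0) 1 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Exact null distribution when at most 25 nonzero, untied differences are
#' available; normal approximation with continuity (and tie) correction
#' otherwise.  Zero differences are dropped; if all differences are zero an
#' error is raised.
#'
#' @param x paired differences, or the first member of each pair when `y`
#'   is given.
#' @param y optional second member of each pair.
#' @return list: `V` (signed-rank statistic), `p` (two-sided), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero")
  ex <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = ex, correct = TRUE))
  list(V = unname(ht$statistic), p = ht$p.value, exact = ex)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional test; the two-sided p-value is the sum of hypergeometric
#' probabilities not exceeding that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when the smaller sample has at most 8 untied observations, normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param x,y the two samples (non-empty).
#' @return list: `U`, `p` (two-sided), `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ex <- min(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = ex, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = ex)
}

#' Sample size for a paired Wilcoxon signed-rank test
#'
#' Smallest total number of pairs reaching the target power for a two-sided
#' matched-pairs Wilcoxon signed-rank test, using the
#' asymptotic-relative-efficiency correction of the paired noncentral-t
#' sample size: the t-test power routine is evaluated at the effective
#' sample size `n' = n * ARE`, with ARE = 3/pi for a normal parent
#' distribution.  The paired effect size is
#' `dz = delta / sqrt(sd_a^2 + sd_b^2 - 2 * rho * sd_a * sd_b)`.
#'
#' @param delta mean paired difference to detect (same units as the sds).
#' @param sd_a,sd_b group standard deviations.
#' @param rho correlation between the paired groups, in `(-1, 1)`.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return list: `n` (total pairs), `dz`, `achieved_power`, `method`.
#' @export
paired_wilcoxon_sample_size <- function(delta, sd_a, sd_b, rho,
                                        alpha = 0.05, power = 0.80) {
  if (delta <= 0) stop("delta must be positive")
  if (sd_a <= 0 || sd_b <= 0) stop("sds must be positive")
  if (rho <= -1 || rho >= 1) stop("rho must lie in (-1, 1)")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    stop("need 0 < alpha < power < 1")
  sd_diff <- sqrt(sd_a^2 + sd_b^2 - 2 * rho * sd_a * sd_b)
  if (sd_diff == 0) stop("difference sd is zero for these sds and rho")
  dz <- delta / sd_diff
  are <- 3 / pi
  pow_at <- function(n) {
    np <- n * are
    if (np <= 1.5) return(0)
    ncp <- dz * sqrt(np)
    df <- np - 1
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  n <- 3
  while (pow_at(n) < power) {
    n <- n + 1
    if (n > 1e6) stop("no attainable sample size below 1e6")
  }
  list(n = n, dz = dz, achieved_power = pow_at(n),
       method = "noncentral-t with A.R.E. correction 3/pi (normal parent)")
}

#' qPCR fold change between test and reference DNA
#'
#' `logQT = (Ct_test - Ct_reference) / slope` for the test primer; the fold
#' change is `10^(logQT_test - logQT_control)`.  Interpretation bands:
#' 0.8-1.2 two copies, at most 0.7 deletion, 1.3-1.7 duplication.
#'
#' @param ct_test,ct_ref mean Ct of the test primer in test and reference
#'   DNA.
#' @param slope_test standard-curve slope of the test primer (non-zero).
#' @param logqt_control logQT of the control primer.
#' @return list: `fold_change`, `logqt_test`, `interpretation`.
#' @export
qpcr_fold_change <- function(ct_test, ct_ref, slope_test, logqt_control) {
  if (slope_test == 0) stop("slope must be non-zero")
  logqt <- (ct_test - ct_ref) / slope_test
  fc <- 10^(logqt - logqt_control)
  list(fold_change = fc, logqt_test = logqt,
       interpretation = classify_fold_change(fc))
}

#' Interpret a qPCR fold change as a copy-number class
#'
#' @param fc fold change value.
#' @return `"two_copies"`, `"deletion"`, `"duplication"` or
#'   `"indeterminate"`.
#' @export
classify_fold_change <- function(fc) {
  if (fc >= 0.8 && fc <= 1.2) "two_copies"
  else if (fc <= 0.7) "deletion"
  else if (fc >= 1.3 && fc <= 1.7) "duplication"
  else "indeterminate"
}
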