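#' Two-sample t test
#'
#' Pooled-variance (Student) two-sample t by default, with a Welch option;
#' two-tailed p from the t distribution. With zero pooled variance the
#' test degenerates: equal means give `t = 0, p = 1`, unequal means are an
#' error.
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @seealso [ttest_from_summary()] for the (mean, sd, n) entry point.
#' @examples
#' ttest_two_sample(c(1, 2, 3), c(4, 5, 6))$t  # -3.674
#' @export
ttest_two_sample <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(a)),
            all(is.finite(b)))
  ttest_from_summary(mean(a), sd(a), length(a),
                     mean(b), sd(b), length(b), var_equal = var_equal)
}

#' Two-sample t test from summary statistics
#'
#' Same test as [ttest_two_sample()] computed from group means, SDs and
#' sizes — the form needed to recompute published results from reported
#' summary tables.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @param var_equal Pooled variance (default) or Welch-Satterthwaite.
#' @return List with `t`, `df`, `p` and the input summaries.
#' @examples
#' # age comparison of two groups of 20:
#' ttest_from_summary(51.65, 11.25, 20, 51.00, 10.13, 20)$p  # 0.85
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               var_equal = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2; vb <- sd_b^2
  if (var_equal) {
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(va / n_a + vb / n_b)
    df <- (va / n_a + vb / n_b)^2 /
      ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  }
  if (se <= .Machine$double.eps) {
    if (abs(mean_a - mean_b) <= .Machine$double.eps)
      return(list(t = 0, df = df, p = 1, mean_a = mean_a, mean_b = mean_b,
                  sd_a = sd_a, sd_b = sd_b))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom
#' (e.g. for a male/female by group table).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `statistic`, `df = 1`, `p`.
#' @examples
#' chi_square_2x2(matrix(c(11, 14, 9, 6), 2))$statistic  # 0.96
#' @export
chi_square_2x2 <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), sum(m) > 0)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: a marginal total is zero")
  res <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(res$statistic), df = 1,
       p = unname(res$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control: the adjusted value for the
#' i-th smallest p is `min over j >= i of p_(j) * m / j`, capped at 1;
#' hypotheses with adjusted p at most `alpha` are rejected. The
#' adjustment is delegated to [stats::p.adjust()].
#'
#' @param raw_p Vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return List with `adjusted` (same order as input), `reject` (logical)
#'   and `alpha`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.5), 0.05)$adjusted  # 0.03 0.03 0.50
#' @export
fdr_bh <- function(raw_p, alpha = 0.05) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0) || any(raw_p > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(alpha > 0, alpha < 1)
  adjusted <- p.adjust(raw_p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha, alpha = alpha)
}
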