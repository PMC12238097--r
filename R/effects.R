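#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' computed directly from group means, SDs and sizes — the form needed to
#' check published demographic tables, where only summaries are printed.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Tibble with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' # body-height comparison of 9 men vs 11 women
#' welch_t(183.2, 4.5, 9, 169.9, 5.8, 11)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' @rdname welch_t
#' @param x,y Raw samples; summarised and passed to `welch_t()`, so the two
#'   routes agree exactly.
#' @export
welch_t_raw <- function(x, y) {
  welch_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Cohen's d with the average-SD denominator
#'
#' Standardised mean difference `(mean1 - mean2) / ((sd1 + sd2) / 2)`. The
#' average-SD denominator is the default; the pooled-SD variant
#' (`sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`) is available via
#' `denominator = "pooled"`, which then requires the group sizes.
#'
#' @inheritParams welch_t
#' @param denominator `"average"` (default) or `"pooled"`.
#' @return d (sign matches the sign of `mean1 - mean2`).
#' @export
#' @examples
#' cohens_d_avgsd(183.2, 4.5, 169.9, 5.8)
cohens_d_avgsd <- function(mean1, sd1, mean2, sd2,
                           denominator = c("average", "pooled"),
                           n1 = NULL, n2 = NULL) {
  stopifnot(sd1 > 0, sd2 > 0)
  denominator <- match.arg(denominator)
  s <- if (denominator == "average") {
    (sd1 + sd2) / 2
  } else {
    if (is.null(n1) || is.null(n2)) {
      abort("pooled denominator requires n1 and n2")
    }
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  }
  (mean1 - mean2) / s
}

#' Two-group comparison (t, p and effect size)
#'
#' Convenience wrapper producing one demographics-table row: Welch t,
#' Satterthwaite df, two-sided p and average-SD Cohen's d.
#'
#' @inheritParams welch_t
#' @return One-row tibble: `mean1`, `sd1`, `mean2`, `sd2`, `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
group_comparison <- function(mean1, sd1, n1, mean2, sd2, n2) {
  wt <- welch_t(mean1, sd1, n1, mean2, sd2, n2)
  tibble(mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
         t = wt$t, df = wt$df, p = wt$p,
         cohens_d = cohens_d_avgsd(mean1, sd1, mean2, sd2))
}
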