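#' Between-group comparison of one feature with a normality gate
#'
#' Tests both groups for normality with Shapiro-Wilk at `alpha_normality`;
#' if both pass, a two-tailed two-sample t-test (pooled variance by default,
#' Welch via `var_equal = FALSE`) is used, otherwise a two-tailed
#' Mann-Whitney U test (exact when both groups have n < 8 and there are no
#' ties, normal approximation with tie/continuity correction otherwise).
#' A group with zero variance fails the gate by definition.
#'
#' @param values_a,values_b numeric samples of the two groups (each n >= 3).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param var_equal pooled-variance t-test if TRUE (default).
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `test_used`
#'   (`"t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `significant_at_0_05`.
#' @export
compare_groups <- function(values_a, values_b, alpha_normality = 0.05,
                           var_equal = TRUE, alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs n >= 3")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    stop("constant data in both groups")
  }
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  use_t <- normal(values_a) && normal(values_b)
  if (use_t) {
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal,
                        alternative = "two.sided")
    test_used <- "t"
  } else {
    exact <- length(values_a) < 8L && length(values_b) < 8L &&
      !any(duplicated(c(values_a, values_b)))
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE,
                         alternative = "two.sided"))
    test_used <- "mann_whitney"
  }
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       test_used = test_used, statistic = unname(ht$statistic),
       p_value = ht$p.value, significant_at_0_05 = ht$p.value < alpha)
}

#' Per-feature group comparison report
#'
#' Applies [compare_groups()] to every feature column of a feature table
#' (HC as group a, AD as group b), mirroring a per-feature report of group
#' means and two-tailed p-values. No multiple-comparison correction is
#' applied by default; `adjust = "BH"` adds a Benjamini-Hochberg column and
#' flags on the adjusted values.
#'
#' @param table a [feature_table()].
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param var_equal pooled-variance t-test if TRUE (default).
#' @return data.frame with one row per feature: `feature`, `mean_hc`,
#'   `sd_hc`, `mean_ad`, `sd_ad`, `test`, `statistic`, `p_two_tailed`,
#'   `significant_0_05` (and `p_adjusted` when `adjust = "BH"`).
#' @export
feature_report <- function(table, alpha_normality = 0.05, alpha = 0.05,
                           adjust = c("none", "BH"), var_equal = TRUE) {
  adjust <- match.arg(adjust)
  table <- feature_table(table)
  feats <- setdiff(names(table), c("subject_id", "group"))
  hc <- table$group == "HC"
  rows <- lapply(feats, function(f) {
    cg <- compare_groups(table[[f]][hc], table[[f]][!hc],
                         alpha_normality = alpha_normality,
                         var_equal = var_equal, alpha = alpha)
    data.frame(feature = f, mean_hc = cg$mean_a, sd_hc = cg$sd_a,
               mean_ad = cg$mean_b, sd_ad = cg$sd_b, test = cg$test_used,
               statistic = cg$statistic, p_two_tailed = cg$p_value)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_two_tailed, method = "BH")
    out$significant_0_05 <- out$p_adjusted < alpha
  } else {
    out$significant_0_05 <- out$p_two_tailed < alpha
  }
  out
}
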