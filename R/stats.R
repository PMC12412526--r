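# Group-level statistics: normality screening, two-sample comparisons,
# significance labelling.

#' Shapiro-Wilk normality screen
#'
#' Returns the W-test p-value; the pipeline warns (and proceeds with
#' t-tests) when normality is rejected, mirroring the screen-then-t-test
#' workflow.
#'
#' @param x numeric sample, n >= 3, non-constant.
#' @param warn_alpha warn when p falls below this level (default 0.05).
#' @return the p-value, invisibly warns when below `warn_alpha`.
#' @export
normality_check <- function(x, warn_alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) abort("need n >= 3 for the Shapiro-Wilk test")
  if (sd(x) == 0) abort("Shapiro-Wilk test undefined for a constant sample")
  p <- shapiro.test(x)$p.value
  if (p < warn_alpha) {
    warn(sprintf("normality rejected (Shapiro-Wilk p = %.3g); %s",
                 p, "group comparison proceeds with t-tests regardless"))
  }
  p
}

#' Significance label for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#' @param p p-value(s).
#' @export
significance_label <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Two-sample comparison of a metric between groups
#'
#' Equal-variance two-sample t-test by default (Welch via `var_equal =
#' FALSE`), with the usual significance stars. No multiple-testing
#' correction is applied across metrics.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param var_equal pool variances (default TRUE)?
#' @return one-row tibble: n_a, n_b, mean_a, mean_b, sd_a, sd_b, statistic,
#'   p_value, label.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 in each group")
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sd_a = sd(a), sd_b = sd(b),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    label = significance_label(tt$p.value)
  )
}
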