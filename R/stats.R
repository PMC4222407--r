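# Paired comparison procedures: test selection (paired t vs Wilcoxon signed
# rank), percent-change summaries, and effect-vs-age correlation.

#' Paired comparison of a feature between conditions
#'
#' Normality of the paired differences is assessed by Shapiro-Wilk at
#' `alpha_normality`; the Wilcoxon signed-rank test is used for small
#' samples (n < 8) or non-normal differences, the paired t-test otherwise.
#' The Wilcoxon null distribution is exact for n <= 25 when the differences
#' carry no ties or zeros.
#'
#' @param control,treatment paired numeric vectors (same length, n >= 3)
#' @param feature feature name carried into the result
#' @param alpha significance level
#' @param alpha_normality Shapiro-Wilk level for the normality gate
#' @return object of class `comparison_result`
#' @export
paired_compare <- function(control, treatment, feature = "feature",
                           alpha = 0.05, alpha_normality = 0.05) {
  if (length(control) != length(treatment))
    stop("control and treatment must be paired (equal lengths)")
  n <- length(control)
  if (n < 3) stop("need at least 3 pairs")
  diffs <- treatment - control
  sem <- function(x) sd(x) / sqrt(length(x))
  if (all(diffs == diffs[1]) && diffs[1] == 0) {
    return(structure(list(
      feature = feature, n = n,
      control_mean = mean(control), control_sem = sem(control),
      treatment_mean = mean(treatment), treatment_sem = sem(treatment),
      percent_change = 0, test_used = "degenerate", p_value = 1,
      significant = FALSE, degenerate = TRUE), class = "comparison_result"))
  }
  normal_p <- if (sd(diffs) == 0) 0 else stats::shapiro.test(diffs)$p.value
  use_wilcox <- n < 8 || normal_p < alpha_normality
  if (use_wilcox) {
    exact <- n <= 25 && !any(diffs == 0) && !any(duplicated(abs(diffs)))
    ht <- stats::wilcox.test(treatment, control, paired = TRUE, exact = exact)
    test_used <- "wilcoxon_signed_rank"
  } else {
    ht <- stats::t.test(treatment, control, paired = TRUE)
    test_used <- "paired_t"
  }
  pc <- percent_change(mean(control), mean(treatment),
                       direction = if (mean(treatment) >= mean(control))
                         "increase" else "decrease")
  structure(list(
    feature = feature, n = n,
    control_mean = mean(control), control_sem = sem(control),
    treatment_mean = mean(treatment), treatment_sem = sem(treatment),
    percent_change = pc$signed, test_used = test_used,
    p_value = unname(ht$p.value), significant = ht$p.value < alpha,
    degenerate = FALSE), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (n = %d)\n", x$feature, x$n))
  cat(sprintf("  %.2f +/- %.2f vs %.2f +/- %.2f (%+.0f%%)\n",
              x$control_mean, x$control_sem, x$treatment_mean, x$treatment_sem,
              x$percent_change))
  cat(sprintf("  %s: P = %.3g%s\n", x$test_used, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Percent change between group means
#'
#' `100 * |treatment - control| / control`, signed according to the stated
#' direction; the reported value is rounded half-to-even to an integer, the
#' unrounded value is retained.
#'
#' @param control_mean,treatment_mean group means (control > 0)
#' @param direction "increase" or "decrease"
#' @return list with `percent` (rounded integer), `unrounded` and `signed`
#'   (signed unrounded change)
#' @export
percent_change <- function(control_mean, treatment_mean,
                           direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (control_mean <= 0) stop("control mean must be positive")
  raw <- 100 * abs(treatment_mean - control_mean) / control_mean
  list(percent = round(raw), unrounded = raw,
       signed = if (direction == "increase") raw else -raw)
}

#' Correlation of effect size with age
#'
#' Pearson correlation of per-cell effect sizes against animal age, with the
#' two-sided p-value from the t-distribution.
#'
#' @param effect_sizes numeric vector of per-cell effects
#' @param ages numeric vector of ages, days
#' @return list with `r` and `p`
#' @export
effect_age_correlation <- function(effect_sizes, ages) {
  if (length(effect_sizes) != length(ages)) stop("lengths differ")
  if (length(ages) < 3) stop("need at least 3 observations")
  if (sd(effect_sizes) == 0 || sd(ages) == 0)
    stop("correlation undefined for constant input")
  ht <- stats::cor.test(effect_sizes, ages, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Table-shaped report of paired comparisons for a cohort
#'
#' Runs [paired_compare()] for every feature of a paired cohort and returns
#' one row per feature.
#'
#' @param cohort a `paired_cohort` from [generate_paired_cohort()]
#' @return data.frame with means, SEMs, percent change, test and p-value
#' @export
compare_cohort <- function(cohort) {
  feats <- setdiff(names(cohort$control), c("cell", "age"))
  rows <- lapply(feats, function(f) {
    cr <- paired_compare(cohort$control[[f]], cohort$treatment[[f]], feature = f)
    data.frame(feature = f, n = cr$n,
               control_mean = cr$control_mean, control_sem = cr$control_sem,
               treatment_mean = cr$treatment_mean, treatment_sem = cr$treatment_sem,
               percent_change = cr$percent_change, test_used = cr$test_used,
               p_value = cr$p_value, significant = cr$significant)
  })
  do.call(rbind, rows)
}
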