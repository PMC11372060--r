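#' Two-sample Levene's test for equality of variances
#'
#' Classic (mean-centred) Levene: a one-way ANOVA F statistic on the absolute
#' deviations of each observation from its group mean, with p-value from
#' `F(1, n_a + n_b - 2)`. `center = "median"` gives the Brown-Forsythe
#' variant.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param center `"mean"` (classic, default) or `"median"`.
#' @return list with `statistic` (W) and `p_value`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    cr_abort("Levene's test needs n >= 2 per group", "sample_error")
  }
  cfun <- if (center == "mean") mean else stats::median
  z <- c(abs(a - cfun(a)), abs(b - cfun(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  fit <- stats::anova(stats::lm(z ~ g))
  w <- fit[["F value"]][1]
  p <- fit[["Pr(>F)"]][1]
  if (is.na(w)) { # both groups constant: deviations all zero
    w <- 0
    p <- 1
  }
  list(statistic = w, p_value = p)
}

#' Two-sample t-test (pooled or Welch)
#'
#' Pooled-variance Student's t with `n_a + n_b - 2` degrees of freedom when
#' `equal_var = TRUE`, Welch's t with Welch-Satterthwaite degrees of freedom
#' otherwise; two-sided p-value. When both samples have zero variance and
#' equal means the test is vacuous and `t = 0, p = 1` by convention.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param equal_var assume equal variances (Student) or not (Welch).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
two_sample_t <- function(a, b, equal_var = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    cr_abort("t-test needs n >= 2 per group", "sample_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2))
    }
    return(list(statistic = if (mean(a) > mean(b)) Inf else -Inf,
                p_value = 0, df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = equal_var)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Pairwise strain comparison cascade
#'
#' The published decision rule: Levene's test first; if the variances differ
#' significantly (Levene p < `alpha`) use Welch's t-test, otherwise Student's
#' pooled t-test; the difference is called significant when the chosen test's
#' p-value is below `alpha` (0.05 throughout the original analysis).
#'
#' @param a,b numeric samples (e.g. per-well first-cycle periods of two
#'   strains), each n >= 2.
#' @param alpha significance level for both stages (default 0.05).
#' @return object of class `strain_test`: `levene_stat`, `levene_p`,
#'   `test_used` (`"student"` or `"welch"`), `t_stat`, `p`, `df`,
#'   `significant`.
#' @export
compare_strains <- function(a, b, alpha = 0.05) {
  lev <- levene_test(a, b)
  welch <- lev$p_value < alpha
  tt <- two_sample_t(a, b, equal_var = !welch)
  structure(
    list(levene_stat = lev$statistic, levene_p = lev$p_value,
         test_used = if (welch) "welch" else "student",
         t_stat = tt$statistic, p = tt$p_value, df = tt$df,
         significant = tt$p_value < alpha),
    class = "strain_test"
  )
}

#' Comparison matrix over all strain pairs
#'
#' Runs [compare_strains()] for every unordered pair of the supplied groups.
#' No multiple-testing correction is applied by default (matching the
#' original pairwise reporting); `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted column.
#'
#' @param groups named list of numeric vectors (one per strain).
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per pair: `strain_a`, `strain_b`,
#'   `levene_p`, `test_used`, `t`, `p`, (`p_adj`,) `significant`.
#' @export
compare_all_strains <- function(groups, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), !is.null(names(groups)))
  nm <- names(groups)
  if (length(nm) < 2L) cr_abort("need at least two strains", "sample_error")
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    r <- compare_strains(groups[[pairs[1, k]]], groups[[pairs[2, k]]], alpha)
    data.frame(strain_a = pairs[1, k], strain_b = pairs[2, k],
               levene_p = r$levene_p, test_used = r$test_used,
               t = r$t_stat, p = r$p, significant = r$significant)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  }
  out
}
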