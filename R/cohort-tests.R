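# Demographic / clinical comparison tests: Pearson chi-square (no
# continuity correction) for categorical variables, two-sample t-tests
# (pooled or Welch, from raw values or printed summaries) for numeric ones.

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' `df = (r - 1)(c - 1)` and an upper-tail p-value. Expected counts below 5
#' trigger a warning only (the test is still computed), matching common
#' practice for small clinical tables.
#'
#' @param counts A non-negative integer matrix (at least 2 x 2), categories
#'   in rows, arms in columns; or a data frame coercible to one.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `min_expected`.
#' @export
#' @examples
#' # pathological response (complete/partial) by arm
#' chi_square(matrix(c(13, 8, 11, 11), nrow = 2))  # p = 0.432
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("table must be at least 2 x 2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("all-zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  min_exp <- min(ct$expected)
  if (min_exp < 5) {
    warn(sprintf("minimum expected count %.2f < 5; chi-square approximation may be poor",
                 min_exp))
  }
  tibble(statistic = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = ct$p.value,
         min_expected = min_exp)
}

#' Two-sample t-test (raw values)
#'
#' Two-sided comparison of two numeric samples, pooled-variance or Welch.
#'
#' @param x,y Numeric samples (`NA`s dropped), each with >= 2 values.
#' @param variant `"pooled"` (equal variances) or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
t_test2 <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 values per arm")
  if (variant == "pooled" && sd(x) == 0 && sd(y) == 0) {
    abort("zero pooled variance")
  }
  tt <- t.test(x, y, var.equal = (variant == "pooled"),
               alternative = "two.sided")
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Two-sample t-test from printed summaries
#'
#' Computes the two-sided t-test from per-arm mean, SD and n, as printed in
#' a demographics table, without access to the raw values.
#'
#' @param mean1,sd1,n1 Summary statistics of arm 1.
#' @param mean2,sd2,n2 Summary statistics of arm 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @export
#' @examples
#' t_test_summary(24.1, 9.0, 21, 26.6, 6.1, 22)
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per arm")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    if (sp2 <= 0) abort("zero pooled variance")
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    if (v1 + v2 <= 0) abort("zero variance")
    tval <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble(t = tval, df = df, p_value = 2 * pt(-abs(tval), df))
}

#' Arm-comparison table for a cohort
#'
#' Compares two study arms across numeric variables (t-test) and
#' categorical variables (Pearson chi-square without continuity
#' correction), producing one test per variable in the style of a clinical
#' demographics table.
#'
#' @param meta A tibble with one row per sample.
#' @param arm Name of the two-level grouping column.
#' @param numeric_vars Character vector of numeric column names.
#' @param categorical_vars Character vector of categorical column names.
#' @param variant t-test variant for numeric variables.
#' @return A tibble: `variable`, `type`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_arms <- function(meta, arm, numeric_vars = character(),
                         categorical_vars = character(),
                         variant = "pooled") {
  stopifnot(arm %in% names(meta))
  g <- droplevels(factor(meta[[arm]]))
  if (nlevels(g) != 2) abort("`arm` must have exactly two levels")
  rows <- list()
  for (v in numeric_vars) {
    tt <- t_test2(meta[[v]][g == levels(g)[1]], meta[[v]][g == levels(g)[2]],
                  variant = variant)
    rows[[v]] <- tibble(variable = v, type = "numeric", test = "t-test",
                        statistic = tt$t, df = tt$df, p_value = tt$p_value)
  }
  for (v in categorical_vars) {
    tab <- table(meta[[v]], g)
    cs <- chi_square(unclass(tab))
    rows[[v]] <- tibble(variable = v, type = "categorical",
                        test = "chi-square", statistic = cs$statistic,
                        df = cs$df, p_value = cs$p_value)
  }
  list_rbind(rows)
}
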