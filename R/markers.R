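# Univariate biomarker screening: Wilcoxon-Mann-Whitney with BH FDR,
# Cliff's delta effect size, rank-based AUROC, Youden threshold, Pearson
# correlation. Missing values are dropped pairwise per feature.

#' Cliff's delta effect size
#'
#' The difference between the probability that a value from group 1 exceeds
#' a value from group 2 and the reverse probability:
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n1 * n2)`, in \[-1, 1\].
#' Magnitude labels use the conventional thresholds 0.147 (small), 0.33
#' (medium) and 0.474 (large) on `abs(delta)`.
#'
#' @param x,y Numeric values for group 1 and group 2; `NA`s are dropped.
#' @return A list with `delta`, `magnitude`, `n1`, `n2`.
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))  # -5/9, large
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty after removing missing values")
  }
  s <- sign(outer(x, y, "-"))
  delta <- sum(s) / (length(x) * length(y))
  list(delta = delta, magnitude = delta_magnitude(delta),
       n1 = length(x), n2 = length(y))
}

#' @rdname cliffs_delta
#' @param delta A delta value in \[-1, 1\].
#' @export
delta_magnitude <- function(delta) {
  a <- abs(delta)
  cut(a, breaks = c(-Inf, 0.147, 0.33, 0.474, Inf),
      labels = c("negligible", "small", "medium", "large")) |>
    as.character()
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney form of the AUROC: the probability that a random
#' positive-class value outranks a random negative-class value, ties counted
#' one half. Identical to `U / (n1 * n2)` with the positive class as group 1.
#'
#' @param values Numeric scores; `NA`s dropped with their labels.
#' @param labels Binary class labels aligned with `values`.
#' @param positive The label treated as positive (larger scores = more
#'   positive); defaults to the second factor level.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)  # 0.75
auroc <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- factor(labels[keep])
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) abort("exactly two classes required")
  positive <- as.character(positive %||% levels(labels)[2])
  pos <- labels == positive
  if (!any(pos) || all(pos)) abort("both classes must be present")
  r <- rank(values)
  n1 <- sum(pos); n2 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Wilcoxon-Mann-Whitney test
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration) when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used. The
#' `U` statistic is oriented as the number of `(x, y)` pairs with `x > y`
#' (ties half).
#'
#' @param x,y Numeric samples; `NA`s dropped.
#' @param mode `"auto"` (rule above), `"exact"` or `"approximate"`.
#' @return A list with `u_statistic`, `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 20) && !ties,
    exact = TRUE,
    approximate = FALSE
  )
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(u_statistic = unname(wt$statistic),
       p_value = wt$p.value,
       n1 = length(x), n2 = length(y),
       method = if (exact && !ties) "exact" else "normal approximation")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR q-values `q_i = min_(j >= i) p_(j) * m / j`, capped at 1 and
#' returned in the input order. `NA` p-values are preserved as `NA` and do
#' not count toward the family size.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Youden-optimal decision threshold
#'
#' Scans the midpoints of consecutive sorted unique score values (plus
#' outer sentinels) and returns the cut maximizing Youden's
#' `J = sensitivity + specificity - 1`, calling scores above the threshold
#' positive. Ties are broken toward higher specificity (and then toward the
#' higher threshold).
#'
#' @inheritParams auroc
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
best_threshold <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) != 2) abort("exactly two classes required")
  positive <- as.character(positive %||% levels(labels)[2])
  pos <- labels == positive
  if (!any(pos) || all(pos)) abort("both classes must be present")
  u <- sort(unique(values))
  cuts <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  stats <- map(cuts, function(thr) {
    pred_pos <- values > thr
    sens <- sum(pred_pos & pos) / sum(pos)
    spec <- sum(!pred_pos & !pos) / sum(!pos)
    c(thr = thr, sens = sens, spec = spec, j = sens + spec - 1)
  })
  m <- do.call(rbind, stats)
  best <- which(m[, "j"] == max(m[, "j"]))
  if (length(best) > 1) best <- best[order(-m[best, "spec"], -m[best, "thr"])][1]
  list(threshold = unname(m[best, "thr"]),
       sensitivity = unname(m[best, "sens"]),
       specificity = unname(m[best, "spec"]),
       youden_j = unname(m[best, "j"]))
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation on pairwise-complete observations with the
#' two-sided t-transform p-value (`n - 2` degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one of the variables")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Univariate screening of a feature table
#'
#' Runs the full per-feature battery of this package for a two-group
#' contrast: Wilcoxon-Mann-Whitney p, BH q over the screened family,
#' Cliff's delta with magnitude, and AUROC. Missing values are dropped
#' pairwise per feature, and per-feature group sizes are reported. Group 1
#' (the delta orientation and the AUROC positive class) is the `positive`
#' class, so e.g. a marker lower in the positive class has negative delta
#' and AUROC below 0.5.
#'
#' @param features A tibble with a `sample_id` column and one numeric column
#'   per feature (bins, metabolites or cytokines).
#' @param meta A tibble with `sample_id` and the label column.
#' @param label Name of the label column in `meta` (string).
#' @param positive Label value treated as group 1 / positive class.
#' @return A tibble, one row per feature: `feature`, `n1`, `n2`,
#'   `u_statistic`, `p_value`, `q_value`, `cliffs_delta`, `delta_magnitude`,
#'   `auroc`, sorted by `p_value`.
#' @export
screen_markers <- function(features, meta, label, positive) {
  stopifnot("sample_id" %in% names(features), "sample_id" %in% names(meta),
            label %in% names(meta))
  df <- left_join(features, meta[c("sample_id", label)], by = "sample_id")
  lab <- factor(df[[label]])
  if (!positive %in% levels(lab)) {
    abort(sprintf("positive class '%s' not found in '%s'", positive, label))
  }
  feats <- setdiff(names(features), "sample_id")
  res <- map(feats, function(f) {
    v <- df[[f]]
    keep <- !is.na(v) & !is.na(lab)
    g1 <- v[keep & lab == positive]
    g2 <- v[keep & lab != positive]
    if (length(g1) == 0 || length(g2) == 0) {
      return(tibble(feature = f, n1 = length(g1), n2 = length(g2),
                    u_statistic = NA_real_, p_value = NA_real_,
                    cliffs_delta = NA_real_, delta_magnitude = NA_character_,
                    auroc = NA_real_))
    }
    mw <- mann_whitney(g1, g2)
    cd <- cliffs_delta(g1, g2)
    au <- auroc(v[keep], lab[keep] == positive, positive = "TRUE")
    tibble(feature = f, n1 = cd$n1, n2 = cd$n2,
           u_statistic = mw$u_statistic, p_value = mw$p_value,
           cliffs_delta = cd$delta, delta_magnitude = cd$magnitude,
           auroc = au)
  })
  out <- list_rbind(res)
  out$q_value <- bh_adjust(out$p_value)
  out |>
    select("feature", "n1", "n2", "u_statistic", "p_value", "q_value",
           "cliffs_delta", "delta_magnitude", "auroc") |>
    arrange(.data$p_value)
}
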