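# Biomarker fusion: weighted linear combination of two standardized
# features (e.g. a cytokine in pg/mL and a metabolite in arbitrary units),
# and logic-OR combination of two classifiers' calls.

#' Fit a two-feature weighted linear combination model
#'
#' Both features are z-scored on the training data (percentage weights
#' across features measured in different units are only meaningful on a
#' common scale), oriented so that each points positively toward the
#' positive class, then combined as `w1 * z1 + w2 * z2` with
#' `|w1| + |w2| = 1`. Weights are found either by an exhaustive grid scan of
#' `w1` in \[0, 1\] (step 0.001) maximizing the training AUROC of the
#' combined score (default), or from the two-feature Fisher discriminant
#' coefficients. The decision threshold is the Youden-optimal cut on the
#' combined training scores.
#'
#' @param data A tibble containing the two feature columns and the label
#'   column (and optionally `sample_id`). Rows with a missing value in
#'   either feature are dropped from fitting.
#' @param features Character vector of exactly two feature column names.
#' @param label Name of the label column.
#' @param positive Label value of the positive class.
#' @param method `"grid"` (AUROC-maximizing scan) or `"lda"` (Fisher
#'   coefficients via [MASS::lda()], normalized to `|w1| + |w2| = 1`).
#' @param grid_step Scan resolution for the grid method.
#' @return An object of class `fusion_model`: `features`, `center`, `scale`,
#'   `sign` (orientation of each feature), `weights` (magnitudes, sum 1),
#'   `threshold`, `positive`, `method`, plus training diagnostics
#'   `auroc` (resubstitution), `cv_auroc` (leave-one-out rescored AUROC),
#'   `sensitivity`, `specificity`, `accuracy`, `n`.
#' @export
fit_linear_combo <- function(data, features, label, positive,
                             method = c("grid", "lda"), grid_step = 0.001) {
  method <- match.arg(method)
  if (length(features) != 2) abort("exactly two features required")
  stopifnot(all(features %in% names(data)), label %in% names(data))
  lab <- factor(data[[label]])
  if (!positive %in% levels(lab)) abort("positive class not present")
  keep <- complete.cases(data[features]) & !is.na(lab)
  x <- as.matrix(data[keep, features]); lab <- droplevels(lab[keep])
  y <- lab == positive
  if (sum(y) < 3 || sum(!y) < 3) abort("need >= 3 complete samples per class")
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  if (any(scl == 0)) abort("degenerate feature with zero variance")
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  # orient each feature positively toward the positive class
  sgn <- map_dbl(1:2, function(j) if (auroc(z[, j], y, positive = "TRUE") >= 0.5) 1 else -1)
  zo <- sweep(z, 2, sgn, "*")
  if (method == "grid") {
    w1 <- seq(0, 1, by = grid_step)
    aucs <- map_dbl(w1, function(w) {
      auroc(w * zo[, 1] + (1 - w) * zo[, 2], y, positive = "TRUE")
    })
    ties <- which(aucs >= max(aucs) - 1e-12)
    if (length(ties) > 1) {
      # AUROC plateaus (e.g. a perfectly separating feature): refine by the
      # standardized mean separation of the combined score, which collapses
      # the tie onto the most discriminative mix
      sep <- map_dbl(ties, function(i) {
        s <- w1[i] * zo[, 1] + (1 - w1[i]) * zo[, 2]
        v <- (sum((s[y] - mean(s[y]))^2) + sum((s[!y] - mean(s[!y]))^2)) /
          (length(s) - 2)
        (mean(s[y]) - mean(s[!y])) / sqrt(max(v, 1e-300))
      })
      best <- ties[which.max(sep)]
    } else {
      best <- ties
    }
    w <- c(w1[best], 1 - w1[best])
  } else {
    ld <- MASS::lda(zo, grouping = y)
    coefs <- drop(ld$scaling[, 1])
    if (mean(zo[y, ] %*% coefs) < mean(zo[!y, ] %*% coefs)) coefs <- -coefs
    w <- abs(coefs) / sum(abs(coefs)) * sign(coefs)
    # after orientation the Fisher coefficients are expected non-negative;
    # fold any residual sign into the orientation vector
    sgn <- sgn * ifelse(w < 0, -1, 1)
    w <- abs(w)
    zo <- sweep(z, 2, sgn, "*")
  }
  score <- drop(zo %*% w)
  thr <- best_threshold(score, y, positive = "TRUE")
  model <- structure(
    list(features = features, center = ctr, scale = scl, sign = sgn,
         weights = w, threshold = thr$threshold, positive = positive,
         negative = setdiff(levels(lab), positive)[1],
         method = method,
         auroc = auroc(score, y, positive = "TRUE"),
         sensitivity = thr$sensitivity, specificity = thr$specificity,
         accuracy = mean((score > thr$threshold) == y),
         n = length(y)),
    class = "fusion_model"
  )
  model$cv_auroc <- loo_combo_auroc(x, y, method, grid_step)
  model
}

# leave-one-out rescored AUROC of the combination: weights, centering and
# orientation refitted without the held-out sample
loo_combo_auroc <- function(x, y, method, grid_step) {
  n <- length(y)
  sc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]; yi <- y[-i]
    if (sum(yi) < 3 || sum(!yi) < 3) return(NA_real_)
    ctr <- colMeans(xi); scl <- apply(xi, 2, sd)
    if (any(scl == 0)) return(NA_real_)
    z <- sweep(sweep(xi, 2, ctr), 2, scl, "/")
    sgn <- map_dbl(1:2, function(j) if (auroc(z[, j], yi, positive = "TRUE") >= 0.5) 1 else -1)
    zo <- sweep(z, 2, sgn, "*")
    if (method == "grid") {
      w1 <- seq(0, 1, by = max(grid_step, 0.01))
      aucs <- map_dbl(w1, function(w) auroc(w * zo[, 1] + (1 - w) * zo[, 2],
                                            yi, positive = "TRUE"))
      w <- c(w1[which.max(aucs)], 1 - w1[which.max(aucs)])
    } else {
      ld <- MASS::lda(zo, grouping = yi)
      coefs <- drop(ld$scaling[, 1])
      if (mean(zo[yi, ] %*% coefs) < mean(zo[!yi, ] %*% coefs)) coefs <- -coefs
      w <- abs(coefs) / sum(abs(coefs))
    }
    zq <- (x[i, ] - ctr) / scl * sgn
    sc[i] <- sum(w * zq)
  }
  auroc(sc, y, positive = "TRUE")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model: %s> %.1f%% %s + %.1f%% %s, threshold %.3f, AUROC %.3f (positive = %s)\n",
              x$method, 100 * x$weights[1], x$features[1],
              100 * x$weights[2], x$features[2], x$threshold, x$auroc,
              x$positive))
  invisible(x)
}

#' Score and classify samples with a fusion model
#'
#' Applies the training standardization, orientation and weights to new
#' data. A sample missing either feature gets a missing score and
#' prediction (propagated, with a message).
#'
#' @param model A [fit_linear_combo()] model.
#' @param data A tibble containing the model's feature columns (and
#'   optionally `sample_id`).
#' @return A tibble with `sample_id` (if present), `score`, and `pred`
#'   (positive/negative class label; `NA` when the score is missing).
#' @export
score_linear_combo <- function(model, data) {
  stopifnot(inherits(model, "fusion_model"))
  stopifnot(all(model$features %in% names(data)))
  x <- as.matrix(data[model$features])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  zo <- sweep(z, 2, model$sign, "*")
  score <- drop(zo %*% model$weights)
  if (anyNA(score)) {
    inform(sprintf("%d sample(s) missing a feature: score and prediction set to NA",
                   sum(is.na(score))))
  }
  out <- tibble(
    score = score,
    pred = ifelse(is.na(score), NA_character_,
                  ifelse(score > model$threshold, model$positive,
                         model$negative))
  )
  if ("sample_id" %in% names(data)) {
    out <- bind_cols(data["sample_id"], out)
  }
  out
}

#' @export
predict.fusion_model <- function(object, newdata, ...) {
  score_linear_combo(object, newdata)
}

#' Logic-OR combination of two binary predictions
#'
#' A sample is called positive if either model (or both) calls it positive.
#' A missing call in one input counts as a negative vote in that input, so
#' samples covered by only one model still receive a prediction; the number
#' of such substitutions is reported with a message.
#'
#' @param pred_a,pred_b Tibbles with columns `sample_id` and `pred`
#'   (class labels), or logical vectors of equal length.
#' @param positive The positive class label (required for labelled input).
#' @return For tibble input, a tibble `sample_id`, `pred`; for logical
#'   input, a logical vector.
#' @export
#' @examples
#' logic_or_predict(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE))
logic_or_predict <- function(pred_a, pred_b, positive = NULL) {
  if (is.logical(pred_a) && is.logical(pred_b)) {
    if (length(pred_a) != length(pred_b)) abort("inputs must align")
    na_votes <- sum(is.na(pred_a)) + sum(is.na(pred_b))
    if (na_votes > 0) inform(sprintf("%d missing vote(s) treated as negative", na_votes))
    a <- !is.na(pred_a) & pred_a
    b <- !is.na(pred_b) & pred_b
    return(a | b)
  }
  stopifnot(is.data.frame(pred_a), is.data.frame(pred_b),
            !is.null(positive))
  ids <- union(pred_a$sample_id, pred_b$sample_id)
  if (length(intersect(pred_a$sample_id, pred_b$sample_id)) == 0) {
    abort("prediction tables share no sample ids")
  }
  a <- pred_a$pred[match(ids, pred_a$sample_id)]
  b <- pred_b$pred[match(ids, pred_b$sample_id)]
  or <- logic_or_predict(!is.na(a) & a == positive, !is.na(b) & b == positive)
  tibble(sample_id = ids,
         pred = ifelse(or, positive, paste0("not_", positive)))
}

#' Confusion counts and summary proportions
#'
#' Tabulates predictions against truth for a stated positive class and
#' reports sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/n`.
#'
#' @param pred,truth Vectors of class labels (or logicals), aligned.
#' @param positive Positive class label (`TRUE` for logical input).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
#' @examples
#' # 22 subjects, 8 true relapses all called, 1 of 14 non-relapses miscalled
#' confusion(rep(c(TRUE, TRUE, FALSE), c(8, 1, 13)),
#'           rep(c(TRUE, FALSE), c(8, 14)), positive = TRUE)
confusion <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` must align")
  pred <- as.character(pred); truth <- as.character(truth)
  positive <- as.character(positive)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(pred))
}

#' Reference fusion-weight presets
#'
#' Published-style weight mixes for the two fusion models this package
#' targets: the response model combining TNF-alpha with valine
#' (78.4% / 21.6%) and the relapse model combining IL-2 with IL-10
#' (96.1% / 3.9%). These are weight presets, not fitted models: combine
#' them with a standardization learned from your own data via
#' [preset_fusion_model()].
#'
#' @return A tibble with columns `model`, `feature_1`, `feature_2`,
#'   `weight_1`, `weight_2`, `positive_hint`.
#' @export
preset_fusion_weights <- function() {
  tibble(
    model = c("response_tnfa_valine", "relapse_il2_il10"),
    feature_1 = c("TNFa", "IL2"),
    feature_2 = c("valine", "IL10"),
    weight_1 = c(0.784, 0.961),
    weight_2 = c(0.216, 0.039),
    positive_hint = c("complete response (higher TNF-alpha, lower valine)",
                      "disease-free (higher IL-2 and IL-10)")
  )
}

#' Build a fusion model from preset weights and training data
#'
#' Uses a fixed weight mix (e.g. a row of [preset_fusion_weights()]) but
#' learns standardization, orientation and the Youden threshold from the
#' supplied data, so the preset is usable without refitting the weights.
#'
#' @inheritParams fit_linear_combo
#' @param weights Numeric length-2 weight magnitudes; normalized to sum 1.
#' @return A `fusion_model`.
#' @export
preset_fusion_model <- function(data, features, weights, label, positive) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be two non-negative values")
  }
  m <- fit_linear_combo(data, features, label, positive, method = "grid",
                        grid_step = 0.5)   # cheap scaffold fit
  m$weights <- weights / sum(weights)
  m$method <- "preset"
  lab <- factor(data[[label]])
  keep <- complete.cases(data[m$features]) & !is.na(lab)
  score <- drop(sweep(sweep(as.matrix(data[keep, m$features]), 2, m$center),
                      2, m$scale, "/") %*% (m$sign * m$weights))
  y <- lab[keep] == positive
  thr <- best_threshold(score, y, positive = "TRUE")
  m$threshold <- thr$threshold
  m$sensitivity <- thr$sensitivity
  m$specificity <- thr$specificity
  m$accuracy <- mean((score > thr$threshold) == y)
  m$auroc <- auroc(score, y, positive = "TRUE")
  m$cv_auroc <- NA_real_
  m
}
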