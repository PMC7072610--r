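# Cross-validation and permutation significance for the PCA-CA-kNN
# classifier. Every fold refits the whole pipeline (centering, PCA, CA) on
# the training part only, so the held-out samples never leak into the model.

.pcaca_fit <- function(x, labels, n_pc) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = n_pc)
  loadings <- sv$v
  scores <- xc %*% loadings
  ca <- fit_ca(scores, labels)
  list(center = ctr, loadings = loadings, ca = ca$directions,
       train_scores = scores %*% ca$directions, train_labels = labels)
}

.pcaca_predict <- function(fit, xnew, k) {
  q <- sweep(xnew, 2, fit$center) %*% fit$loadings %*% fit$ca
  knn_vote(fit$train_scores, fit$train_labels, q, k)
}

# Precompute the label-independent part of every leave-one-out fold:
# centering and PCA depend on the training rows only, never on labels, so
# a permutation test can reuse these fold projections and refit only the
# (label-dependent) canonical analysis and kNN vote.
.loocv_folds <- function(x, n_pc) {
  n <- nrow(x)
  lapply(seq_len(n), function(i) {
    xtr <- x[-i, , drop = FALSE]
    ctr <- colMeans(xtr)
    xc <- sweep(xtr, 2, ctr)
    v <- svd(xc, nu = 0, nv = n_pc)$v
    list(scores_train = xc %*% v,
         score_test = (x[i, ] - ctr) %*% v)
  })
}

.loocv_predict <- function(folds, labels, k) {
  n <- length(folds)
  labels <- factor(labels)
  li <- as.integer(labels)
  nl <- nlevels(labels)
  lv <- levels(labels)
  k <- min(k, n - 1L)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- li[-i]
    if (any(tabulate(tr, nbins = nl) == 0)) {
      abort("a class vanished from a training fold; need >= 2 samples per class")
    }
    f <- folds[[i]]
    if (nl == 2) {
      # lean two-group canonical step: Fisher direction in PC-score space
      S <- f$scores_train
      i1 <- tr == 1L
      m1 <- colMeans(S[i1, , drop = FALSE])
      m2 <- colMeans(S[!i1, , drop = FALSE])
      W <- crossprod(sweep(S[i1, , drop = FALSE], 2, m1)) +
        crossprod(sweep(S[!i1, , drop = FALSE], 2, m2))
      W <- W + diag(1e-8 * max(sum(diag(W)), .Machine$double.eps), ncol(S))
      d <- solve(W, m1 - m2)
      s_tr <- drop(S %*% d)
      s_te <- drop(f$score_test %*% d)
      ord <- order((s_tr - s_te)^2)
      nb <- tr[ord[seq_len(k)]]
      counts <- tabulate(nb, nbins = 2L)
      pred[i] <- lv[if (counts[1] == counts[2]) nb[1] else which.max(counts)]
    } else {
      tr_lab <- droplevels(labels[-i])
      ca <- fit_ca(f$scores_train, tr_lab)$directions
      pred[i] <- as.character(
        knn_vote(f$scores_train %*% ca, tr_lab, f$score_test %*% ca, k)
      )
    }
  }
  pred
}

classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(truth))
}

new_cv_report <- function(per_sample, positive, scheme, extra = list()) {
  m <- classification_metrics(per_sample$truth, per_sample$pred, positive)
  structure(
    c(list(per_sample = per_sample,
           sensitivity = unname(m["sensitivity"]),
           specificity = unname(m["specificity"]),
           accuracy = unname(m["accuracy"]),
           positive = positive, scheme = scheme),
      extra),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s> sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%% (positive = %s)\n",
              x$scheme, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy, x$positive))
  invisible(x)
}

validate_cv_args <- function(x, labels, n_pc, k) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("need >= 2 classes")
  if (any(table(labels) < 2)) abort("every class needs >= 2 samples")
  n_fold <- nrow(x) - 1L
  if (n_pc > min(n_fold - 1L, ncol(x))) {
    abort(sprintf("`n_pc` = %d too large for %d-sample folds with %d features",
                  n_pc, n_fold, ncol(x)))
  }
  if (k > n_fold) {
    warn(sprintf("k = %d exceeds fold size %d; clipped", k, n_fold))
    k <- n_fold
  }
  list(labels = labels, k = k)
}

#' Leave-one-out cross-validation of PCA-CA-kNN
#'
#' Each sample in turn is held out; the entire pipeline (centering, PCA,
#' canonical analysis, kNN) is refitted on the remaining samples and a
#' prediction made for the held-out one. Sensitivity, specificity and
#' accuracy are computed from the pooled out-of-fold predictions.
#'
#' @inheritParams fit_pcaca_knn
#' @return A `cv_report` with the out-of-fold predictions (`per_sample`),
#'   `sensitivity`, `specificity`, `accuracy`, and `scheme = "loocv"`.
#' @export
loocv <- function(x, labels, n_pc = 3, k = 5, positive = NULL) {
  x <- as_feature_matrix(x)
  v <- validate_cv_args(x, labels, n_pc, k)
  labels <- v$labels; k <- v$k
  positive <- positive %||% levels(labels)[min(2, nlevels(labels))]
  n <- nrow(x)
  pred <- .loocv_predict(.loocv_folds(x, n_pc), labels, k)
  per_sample <- tibble(
    sample = rownames(x) %||% as.character(seq_len(n)),
    truth = as.character(labels),
    pred = pred
  )
  new_cv_report(per_sample, positive, "loocv",
                list(n_pc = n_pc, k = k))
}

#' Monte Carlo cross-validation of PCA-CA-kNN
#'
#' Repeated stratified random train/test splits; the pipeline is refitted on
#' each training split and metrics are averaged over repetitions.
#'
#' @inheritParams loocv
#' @param train_fraction Fraction of each class used for training, in (0, 1).
#' @param n_reps Number of random splits.
#' @param seed Integer seed; the same seed reproduces the report exactly.
#' @return A `cv_report` with `scheme = "mccv"`; `per_sample` pools all test
#'   predictions across repetitions (column `rep`), while the headline
#'   metrics are means over repetitions.
#' @export
mccv <- function(x, labels, n_pc = 3, k = 5, train_fraction = 0.8,
                 n_reps = 100, seed = 1, positive = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1)")
  }
  x <- as_feature_matrix(x)
  labels <- droplevels(factor(labels))
  positive <- positive %||% levels(labels)[min(2, nlevels(labels))]
  idx_by_class <- split(seq_len(nrow(x)), labels)
  n_train <- map_dbl(idx_by_class, function(ix) floor(length(ix) * train_fraction))
  if (any(n_train < 2) || any(lengths(idx_by_class) - n_train < 1)) {
    abort("stratified split infeasible: need >= 2 train and >= 1 test sample per class")
  }
  rng <- local_rng(seed)
  reps <- map(seq_len(n_reps), function(r) {
    tr <- unlist(map2(idx_by_class, n_train, function(ix, nt) sample(ix, nt)))
    te <- setdiff(seq_len(nrow(x)), tr)
    fit <- .pcaca_fit(x[tr, , drop = FALSE], droplevels(labels[tr]), n_pc)
    pred <- .pcaca_predict(fit, x[te, , drop = FALSE], min(k, length(tr)))
    tibble(rep = r,
           sample = (rownames(x) %||% as.character(seq_len(nrow(x))))[te],
           truth = as.character(labels[te]), pred = as.character(pred))
  })
  per_sample <- list_rbind(reps)
  rep_metrics <- per_sample |>
    group_by(.data$rep) |>
    summarise(as_tibble(as.list(classification_metrics(.data$truth, .data$pred,
                                                       positive))),
              .groups = "drop")
  rep_out <- new_cv_report(per_sample, positive, "mccv",
                           list(n_pc = n_pc, k = k,
                                train_fraction = train_fraction,
                                n_reps = n_reps, seed = seed,
                                rep_metrics = rep_metrics))
  # headline metrics are the mean over repetitions, not the pooled counts
  rep_out$sensitivity <- mean(rep_metrics$sensitivity, na.rm = TRUE)
  rep_out$specificity <- mean(rep_metrics$specificity, na.rm = TRUE)
  rep_out$accuracy <- mean(rep_metrics$accuracy)
  rep_out
}

#' Permutation test for cross-validated accuracy
#'
#' Class labels are permuted uniformly `n_perm` times; the full LOOCV
#' accuracy is recomputed for each permutation, and the p-value is the
#' add-one estimator `(#\{null >= observed\} + 1) / (n_perm + 1)`, which is
#' never exactly zero and is bounded below by `1/(n_perm + 1)`.
#'
#' @inheritParams loocv
#' @param n_perm Number of label permutations (1000 for a reportable
#'   p-value; fewer for quick checks).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `perm_test`: `observed_accuracy`,
#'   `null_accuracies` (length `n_perm`), `p_value`, plus the observed
#'   `cv_report`.
#' @export
permutation_test <- function(x, labels, n_pc = 3, k = 5, n_perm = 1000,
                             seed = 1, positive = NULL) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  x <- as_feature_matrix(x)
  labels <- droplevels(factor(labels))
  observed <- loocv(x, labels, n_pc = n_pc, k = k, positive = positive)
  folds <- .loocv_folds(x, n_pc)
  truth <- as.character(labels)
  local_rng(seed)
  null_acc <- map_dbl(seq_len(n_perm), function(i) {
    perm <- sample(labels)
    mean(.loocv_predict(folds, perm, min(k, nrow(x) - 1L)) ==
           as.character(perm))
  })
  p <- (sum(null_acc >= observed$accuracy) + 1) / (n_perm + 1)
  structure(
    list(observed_accuracy = observed$accuracy,
         null_accuracies = null_acc,
         p_value = p,
         n_perm = n_perm,
         seed = seed,
         cv_report = observed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> observed LOOCV accuracy %.3f, p = %.4g (%d permutations)\n",
              x$observed_accuracy, x$p_value, x$n_perm))
  invisible(x)
}

#' Choose the number of principal components by LOOCV accuracy
#'
#' Evaluates LOOCV accuracy over a candidate range and returns the smallest
#' number of components whose accuracy equals the maximum over the range
#' (ties resolve to the most parsimonious model).
#'
#' @inheritParams loocv
#' @param candidates Integer vector of candidate component counts.
#' @param nested If `TRUE`, also report the per-fold (nested) selection and
#'   the optimism gap between whole-data selection and nested accuracy; see
#'   Details.
#' @details With `nested = TRUE`, component count is re-selected inside each
#'   leave-one-out fold using only that fold's training data, and the
#'   held-out accuracy of that honest procedure is reported alongside. The
#'   whole-data selection mirrors common chemometrics practice but is mildly
#'   optimistic; the gap between the two is returned so it can be inspected.
#' @return An integer (the selected count) with attributes `accuracies`
#'   (named vector over candidates) and, if `nested`, `nested_accuracy` and
#'   `optimism_gap`.
#' @export
select_n_components <- function(x, labels, k = 5, candidates = 1:10,
                                nested = FALSE, positive = NULL) {
  if (length(candidates) == 0) abort("empty candidate range")
  x <- as_feature_matrix(x)
  labels <- droplevels(factor(labels))
  candidates <- sort(unique(as.integer(candidates)))
  n_max <- min(nrow(x) - 2L, ncol(x))
  if (any(candidates < 1) || any(candidates > n_max)) {
    abort(sprintf("candidates must lie in 1..%d", n_max))
  }
  # PCA loadings for a smaller component count are a prefix of the larger
  # ones, so one fold decomposition at max(candidates) serves every entry
  folds <- .loocv_folds(x, max(candidates))
  labels_chr <- as.character(labels)
  acc <- map_dbl(candidates, function(npc) {
    fl <- map(folds, function(f) {
      list(scores_train = f$scores_train[, seq_len(npc), drop = FALSE],
           score_test = f$score_test[, seq_len(npc), drop = FALSE])
    })
    mean(.loocv_predict(fl, labels, min(k, nrow(x) - 1L)) == labels_chr)
  })
  names(acc) <- candidates
  best <- candidates[which(acc == max(acc))[1]]
  out <- best
  attr(out, "accuracies") <- acc
  if (nested) {
    n <- nrow(x)
    pred <- character(n)
    for (i in seq_len(n)) {
      xtr <- x[-i, , drop = FALSE]
      ltr <- droplevels(labels[-i])
      inner <- candidates[candidates <= min(nrow(xtr) - 2L, ncol(xtr))]
      acc_i <- map_dbl(inner, function(npc) {
        loocv(xtr, ltr, n_pc = npc, k = k, positive = positive)$accuracy
      })
      npc_i <- inner[which(acc_i == max(acc_i))[1]]
      fit <- .pcaca_fit(xtr, ltr, npc_i)
      pred[i] <- as.character(.pcaca_predict(fit, x[i, , drop = FALSE],
                                             min(k, n - 1L)))
    }
    nested_acc <- mean(pred == as.character(labels))
    attr(out, "nested_accuracy") <- nested_acc
    attr(out, "optimism_gap") <- max(acc) - nested_acc
  }
  out
}

# Deterministic seeding; seeds are kept inside 32-bit integer range.
local_rng <- function(seed) {
  set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  invisible(seed)
}
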