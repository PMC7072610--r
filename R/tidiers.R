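# broom-style tidiers for the package's fitted objects.

#' Tidy a PCA-CA-kNN model
#'
#' One row per feature: the back-projected weight of each bin on the first
#' canonical component (the quantity plotted in a loading plot).
#'
#' @param x A [fit_pcaca_knn()] model.
#' @param ... Unused.
#' @return A tibble: `feature`, `center`, `weight`.
#' @method tidy pcaca_knn
#' @export
tidy.pcaca_knn <- function(x, ...) {
  w <- drop(x$pca_loadings %*% x$ca_directions[, 1])
  centers <- suppressWarnings(as.numeric(sub("^bin_", "", x$feature_names)))
  tibble(feature = x$feature_names, center = centers, weight = w)
}

#' @rdname tidy.pcaca_knn
#' @method glance pcaca_knn
#' @export
glance.pcaca_knn <- function(x, ...) {
  tibble(n = length(x$train_labels),
         n_features = length(x$feature_names),
         n_pc = x$n_pc,
         n_ca = ncol(x$ca_directions),
         k = x$k,
         positive = x$positive)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report` from [loocv()] or [mccv()].
#' @param ... Unused.
#' @return `tidy()`: the per-sample out-of-fold predictions. `glance()`:
#'   one row with `scheme`, `sensitivity`, `specificity`, `accuracy`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$per_sample

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(scheme = x$scheme, sensitivity = x$sensitivity,
         specificity = x$specificity, accuracy = x$accuracy,
         positive = x$positive)
}

#' Tidy a permutation test
#'
#' @param x A `perm_test` from [permutation_test()].
#' @param ... Unused.
#' @return `tidy()`: one row per permutation with its null accuracy.
#'   `glance()`: observed accuracy, p-value and permutation count.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null_accuracies),
         null_accuracy = x$null_accuracies)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(observed_accuracy = x$observed_accuracy,
         p_value = x$p_value,
         n_perm = x$n_perm)
}

#' Tidy a fusion model
#'
#' @param x A `fusion_model` from [fit_linear_combo()].
#' @param ... Unused.
#' @return `tidy()`: one row per feature with its weight (share of the
#'   combination), orientation sign and training standardization.
#'   `glance()`: AUROC (resubstitution and leave-one-out), threshold and
#'   training confusion metrics.
#' @method tidy fusion_model
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble(feature = x$features,
         weight = x$weights,
         sign = x$sign,
         center = unname(x$center),
         scale = unname(x$scale))
}

#' @rdname tidy.fusion_model
#' @method glance fusion_model
#' @export
glance.fusion_model <- function(x, ...) {
  tibble(method = x$method,
         auroc = x$auroc,
         cv_auroc = x$cv_auroc,
         threshold = x$threshold,
         sensitivity = x$sensitivity,
         specificity = x$specificity,
         accuracy = x$accuracy,
         n = x$n,
         positive = x$positive)
}
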