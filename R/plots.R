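# ggplot2 figures: canonical score plots, loading plots, ROC curves,
# permutation null distributions.

#' Score plot of a PCA-CA-kNN model
#'
#' For two-group models canonical analysis yields a single axis; the
#' vertical axis of the familiar two-dimensional score plot is the first
#' residual principal component orthogonalized against that canonical
#' direction (classification itself uses the canonical dimensions only).
#'
#' @param object A [fit_pcaca_knn()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcaca_knn
#' @export
autoplot.pcaca_knn <- function(object, ...) {
  cv1 <- object$train_scores[, 1]
  if (ncol(object$ca_directions) >= 2) {
    cv2 <- object$train_scores[, 2]
    ylab <- "CV2"
  } else {
    d1 <- object$ca_directions[, 1]
    resid <- object$pc_scores -
      (object$pc_scores %*% d1) %*% t(d1)
    pr <- svd(resid, nu = 0, nv = 1)$v
    cv2 <- drop(resid %*% pr)
    ylab <- "residual PC1 (orthogonal to CV1)"
  }
  df <- tibble(cv1 = cv1, cv2 = cv2, group = object$train_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$cv1, .data$cv2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "CV1", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Loading plot of the first canonical component
#'
#' Plots the back-projected bin weights against chemical shift, with the
#' ppm axis reversed as in spectral display convention.
#'
#' @param loadings A tibble from [loading_analysis()] (or
#'   [tidy.pcaca_knn()]).
#' @param highlight Optional number of top-ranked bins to mark.
#' @return A ggplot.
#' @export
plot_loadings <- function(loadings, highlight = 10) {
  df <- arrange(loadings, .data$center)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$center, .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$center, yend = 0),
                          linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)",
                  y = "CV1 loading weight") +
    ggplot2::theme_minimal()
  if (!is.null(highlight) && "rank" %in% names(df)) {
    top <- filter(df, .data$rank <= highlight)
    p <- p + ggplot2::geom_point(data = top, colour = "red", size = 1.5)
  }
  p
}

#' ROC curve of a score against binary labels
#'
#' @inheritParams auroc
#' @return A ggplot of the empirical ROC step curve, annotated with the
#'   AUROC.
#' @export
plot_roc <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(factor(labels[keep]))
  positive <- as.character(positive %||% levels(labels)[2])
  pos <- labels == positive
  ord <- order(values, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  au <- auroc(values, labels, positive = positive)
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUROC = %.2f", au)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted-label LOOCV accuracies with the observed
#' accuracy marked.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(acc = object$null_accuracies),
                  ggplot2::aes(.data$acc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_accuracy,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "null LOOCV accuracy",
                  subtitle = sprintf("observed %.3f, p = %.4g",
                                     object$observed_accuracy,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
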