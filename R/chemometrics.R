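# Supervised PCA-CA-kNN: principal-component reduction, canonical (Fisher)
# analysis for group separation, k-nearest-neighbor voting in canonical
# score space.

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), "sample_id")]
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) abort("features must be numeric")
  x
}

#' Principal component analysis by SVD
#'
#' Column-mean-centered PCA of a feature matrix; components ordered by
#' decreasing explained variance. No scaling beyond centering is applied
#' (row normalization is the only scaling used upstream).
#'
#' @param x Feature matrix or data frame (samples x features; a `sample_id`
#'   column is ignored).
#' @param n_pc Number of components to retain; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return A list with `center` (column means), `loadings`
#'   (features x `n_pc`, orthonormal), `scores` (samples x `n_pc`), and
#'   `sdev` (singular-value based standard deviations, all components).
#' @export
fit_pca <- function(x, n_pc) {
  x <- as_feature_matrix(x)
  n_max <- min(nrow(x) - 1L, ncol(x))
  if (n_pc < 1 || n_pc > n_max) {
    abort(sprintf("`n_pc` must be in 1..%d for a %d x %d matrix",
                  n_max, nrow(x), ncol(x)))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  if (sv$d[1] < 1e-12) abort("feature matrix is constant; PCA undefined")
  loadings <- sv$v[, seq_len(n_pc), drop = FALSE]
  list(center = ctr,
       loadings = loadings,
       scores = xc %*% loadings,
       sdev = sv$d / sqrt(max(1, nrow(x) - 1)))
}

#' Canonical (Fisher) analysis of group separation
#'
#' Finds the directions in PC-score space maximizing the ratio of
#' between-group to within-group scatter (canonical variates). At most
#' `n_groups - 1` directions carry a nonzero criterion. The within-group
#' scatter is ridge-regularized by `ridge * trace(W)` on the diagonal so
#' that near-singular folds remain solvable.
#'
#' @param scores Samples x components score matrix.
#' @param labels Group labels (factor or character), >= 2 groups with >= 2
#'   samples each.
#' @param ridge Regularization fraction (default `1e-8`).
#' @return A list with `directions` (components x n_ca, unit columns) and
#'   `eigenvalues` (separation criterion per direction, decreasing).
#' @export
fit_ca <- function(scores, labels, ridge = 1e-8) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) abort("canonical analysis needs >= 2 groups")
  if (any(table(labels) < 2)) abort("every group needs >= 2 samples")
  p <- ncol(scores)
  gm <- rowsum(scores, labels) / as.vector(table(labels))
  overall <- colMeans(scores)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in levels(labels)) {
    xg <- scores[labels == g, , drop = FALSE]
    dg <- sweep(xg, 2, gm[g, ])
    W <- W + crossprod(dg)
    db <- gm[g, ] - overall
    B <- B + nrow(xg) * tcrossprod(db)
  }
  W <- W + diag(ridge * max(sum(diag(W)), .Machine$double.eps), p)
  if (nlevels(labels) == 2) {
    # two groups: the single canonical direction is the Fisher direction
    # W^{-1}(m1 - m2), the closed form of the generalized eigenproblem
    d <- drop(solve(W, gm[1, ] - gm[2, ]))
    dirs <- matrix(d / sqrt(sum(d^2)), ncol = 1)
    lam <- drop(t(dirs) %*% B %*% dirs) / drop(t(dirs) %*% W %*% dirs)
    return(list(directions = dirs, eigenvalues = lam))
  }
  # generalized eigenproblem B v = lambda W v via symmetric whitening
  ew <- eigen(W, symmetric = TRUE)
  wih <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300)), p) %*% t(ew$vectors)
  eb <- eigen(wih %*% B %*% wih, symmetric = TRUE)
  n_ca <- min(nlevels(labels) - 1L, p)
  dirs <- wih %*% eb$vectors[, seq_len(n_ca), drop = FALSE]
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  list(directions = dirs, eigenvalues = eb$values[seq_len(n_ca)])
}

#' Fit the PCA-CA-kNN classifier
#'
#' The pipeline centers the feature matrix, projects into an `n_pc`-dimensional
#' principal-component subspace, applies canonical analysis for supervised
#' separation, and classifies by k-nearest-neighbor vote in canonical score
#' space.
#'
#' @param x Feature matrix or data frame (samples x features; `sample_id`
#'   column ignored).
#' @param labels Class labels, one per sample (2 or more classes).
#' @param n_pc Number of principal components to retain (see
#'   [select_n_components()] for the accuracy-driven choice).
#' @param k Neighbor count for the kNN vote; odd values recommended. Values
#'   larger than the training size are clipped with a warning. Ties in the
#'   vote are broken by the single nearest neighbor's label.
#' @param positive Label of the positive class (for downstream
#'   sensitivity/specificity); defaults to the second factor level.
#' @return An object of class `pcaca_knn` with elements `center`,
#'   `pca_loadings`, `n_pc`, `ca_directions`, `train_scores`, `train_labels`,
#'   `k`, `feature_names`, `positive`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 2), 10))
#' fit <- fit_pcaca_knn(x, rep(c("a", "b"), each = 10), n_pc = 2, k = 3)
#' predict(fit, x)
fit_pcaca_knn <- function(x, labels, n_pc = 3, k = 5, positive = NULL) {
  x <- as_feature_matrix(x)
  labels <- droplevels(factor(labels))
  if (nrow(x) != length(labels)) abort("one label per sample required")
  if (k < 1) abort("`k` must be >= 1")
  if (k %% 2 == 0) warn("even `k` may produce vote ties; ties fall back to the nearest neighbor")
  if (k > nrow(x)) {
    warn(sprintf("k = %d exceeds training size %d; clipped", k, nrow(x)))
    k <- nrow(x)
  }
  pca <- fit_pca(x, n_pc)
  ca <- fit_ca(pca$scores, labels)
  structure(
    list(center = pca$center,
         pca_loadings = pca$loadings,
         n_pc = n_pc,
         ca_directions = ca$directions,
         ca_eigenvalues = ca$eigenvalues,
         pc_scores = pca$scores,
         train_scores = pca$scores %*% ca$directions,
         train_labels = labels,
         k = k,
         feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
         positive = positive %||% levels(labels)[min(2, nlevels(labels))]),
    class = "pcaca_knn"
  )
}

#' @export
print.pcaca_knn <- function(x, ...) {
  cat(sprintf("<pcaca_knn> %d samples, %d features, n_pc = %d, n_ca = %d, k = %d\n",
              nrow(x$train_scores), length(x$feature_names), x$n_pc,
              ncol(x$ca_directions), x$k))
  print(table(x$train_labels))
  invisible(x)
}

project_ca <- function(object, x) {
  x <- as_feature_matrix(x)
  if (ncol(x) != length(object$feature_names)) {
    abort(sprintf("new data has %d features; model expects %d",
                  ncol(x), length(object$feature_names)))
  }
  sweep(x, 2, object$center) %*% object$pca_loadings %*% object$ca_directions
}

knn_vote <- function(train_scores, train_labels, query_scores, k) {
  lv <- levels(train_labels)
  lab_int <- as.integer(train_labels)
  out <- vapply(seq_len(nrow(query_scores)), function(i) {
    d2 <- rowSums(sweep(train_scores, 2, query_scores[i, ])^2)
    ord <- order(d2)
    nb <- lab_int[ord[seq_len(k)]]
    counts <- tabulate(nb, nbins = length(lv))
    top <- which(counts == max(counts))
    if (length(top) > 1L) nb[1] else top
  }, integer(1))
  factor(lv[out], levels = lv)
}

#' Predict class labels with a fitted PCA-CA-kNN model
#'
#' New samples are centered with the training means, projected through the
#' training PCA loadings and canonical directions, and classified by
#' Euclidean kNN vote against the training scores. Vote ties are broken by
#' the nearest single neighbor.
#'
#' @param object A fitted [fit_pcaca_knn()] model.
#' @param newdata Feature matrix or data frame with the model's feature
#'   dimension.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.pcaca_knn <- function(object, newdata, ...) {
  q <- project_ca(object, newdata)
  knn_vote(object$train_scores, object$train_labels, q, object$k)
}

#' Loading analysis of the first canonical component
#'
#' Back-projects the first canonical direction through the PCA loadings into
#' the original bin space, giving a signed discrimination weight per bin, and
#' annotates each bin with the group whose mean is higher. Bins with large
#' `abs(weight)` are the main sources of discrimination.
#'
#' @param model A fitted [fit_pcaca_knn()] model.
#' @param x The feature matrix the model was trained on (used for group
#'   means).
#' @param labels Training labels.
#' @return A tibble with columns `feature` (bin name), `center` (ppm, `NA`
#'   for non-bin features), `weight`, `rank` (1 = largest `abs(weight)`),
#'   `higher_in` (group with the larger mean).
#' @export
loading_analysis <- function(model, x, labels) {
  stopifnot(inherits(model, "pcaca_knn"))
  x <- as_feature_matrix(x)
  labels <- droplevels(factor(labels))
  w <- drop(model$pca_loadings %*% model$ca_directions[, 1])
  gm <- rowsum(x, labels) / as.vector(table(labels))
  higher <- rownames(gm)[apply(gm, 2, which.max)]
  nm <- model$feature_names
  centers <- suppressWarnings(as.numeric(sub("^bin_", "", nm)))
  tibble(feature = nm,
         center = centers,
         weight = w,
         rank = rank(-abs(w), ties.method = "first"),
         higher_in = higher) |>
    arrange(.data$rank)
}
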