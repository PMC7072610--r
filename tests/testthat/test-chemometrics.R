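test_that("fit_pca is a centered SVD with orthonormal loadings", {
  # collinear 2-feature data: one component carries all variance
  set.seed(1)
  t1 <- rnorm(20)
  x <- cbind(t1, 3 * t1)
  p <- fit_pca(x, 1)
  expect_equal(sum(p$sdev[-1]^2) / sum(p$sdev^2), 0, tolerance = 1e-12)

  set.seed(2)
  y <- matrix(rnorm(20), 5, 4)
  full <- fit_pca(y, 4)
  expect_equal(crossprod(full$loadings), diag(4), tolerance = 1e-8)
  # reconstruction with all components recovers the centered matrix
  yc <- sweep(y, 2, colMeans(y))
  expect_equal(full$scores %*% t(full$loadings), yc, tolerance = 1e-8)

  expect_error(fit_pca(y, 5), "n_pc")
  expect_error(fit_pca(matrix(1, 5, 4), 2), "constant")
})

test_that("canonical analysis separates groups and reduces to Fisher LDA", {
  sep <- separable_clouds(n_per = 15, p = 6, gap = 8, seed = 3)
  pca <- fit_pca(sep$x, 2)
  ca <- fit_ca(pca$scores, sep$labels)
  cv1 <- drop(pca$scores %*% ca$directions[, 1])
  expect_true(max(cv1[sep$labels == "a"]) < min(cv1[sep$labels == "b"]) ||
              min(cv1[sep$labels == "a"]) > max(cv1[sep$labels == "b"]))

  # two-group direction is parallel to W^{-1}(m1 - m2) from hand scatter
  s <- pca$scores
  g <- sep$labels == "a"
  m1 <- colMeans(s[g, ]); m2 <- colMeans(s[!g, ])
  W <- crossprod(sweep(s[g, ], 2, m1)) + crossprod(sweep(s[!g, ], 2, m2))
  ref <- solve(W, m1 - m2); ref <- ref / sqrt(sum(ref^2))
  got <- ca$directions[, 1]
  expect_equal(abs(sum(ref * got)), 1, tolerance = 1e-6)

  expect_error(fit_ca(pca$scores, rep("a", 30)), ">= 2 groups")
  expect_error(fit_ca(pca$scores, c("b", rep("a", 29))), ">= 2 samples")
})

test_that("PCA-CA predictions match an independent LDA + 1-NN pipeline", {
  skip_if_not_installed("class")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:20, 1); p <- sample(3:5, 1)
    x <- matrix(rnorm(n * p), n)
    labels <- factor(sample(rep(c("a", "b"), length.out = n)))
    x[labels == "b", 1] <- x[labels == "b", 1] + 1.5
    npc <- min(p, 3)
    fit <- fit_pcaca_knn(x, labels, n_pc = npc, k = 1)
    # independent route: prcomp + MASS::lda + class::knn on LD scores
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    sc <- pr$x[, seq_len(npc), drop = FALSE]
    ld <- MASS::lda(sc, grouping = labels)
    ldsc <- sc %*% ld$scaling
    ref <- class::knn(ldsc, ldsc, labels, k = 1)
    expect_equal(as.character(predict(fit, x)), as.character(ref))
  }
})

test_that("kNN vote behaves at the boundaries", {
  sep <- separable_clouds(n_per = 10, p = 4, gap = 10, seed = 4)
  fit1 <- fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 1)
  # query equal to a training sample with k = 1 returns that label
  expect_equal(as.character(predict(fit1, sep$x[3, , drop = FALSE])), "a")

  # k = training size with balanced classes: global tie resolves to the
  # nearest neighbour's label
  suppressWarnings({
    fit_all <- fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 20)
  })
  expect_equal(as.character(predict(fit_all, sep$x)), sep$labels)

  # separable clouds classify perfectly at training
  fit5 <- fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 5)
  expect_equal(as.character(predict(fit5, sep$x)), sep$labels)

  expect_warning(fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 4), "even")
  expect_warning(fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 99), "clipped")
  expect_error(predict(fit5, sep$x[, 1:3]), "features")
})

test_that("loading analysis recovers a spiked region with the right sign", {
  coh <- generate_cohort(spiked_spec(fold = 3, cv = 0.05), seed = 11)
  xy <- cohort_xy(coh)
  fit <- fit_pcaca_knn(xy$x, xy$labels, n_pc = 2, k = 5)
  la <- loading_analysis(fit, xy$x, xy$labels)
  spiked <- !is.na(la$center) & la$center > 1.23 & la$center < 1.37
  n_spiked <- sum(spiked)
  # the spiked bins occupy the top |weight| ranks
  expect_gte(sum(la$rank[spiked] <= n_spiked), n_spiked - 1)
  # the spiked arm has the larger mean in those bins
  expect_true(all(la$higher_in[spiked & la$rank <= n_spiked] == "B"))

  # null cohort: with zero between-group difference the canonical
  # separation criterion collapses toward the noise floor (the unit-norm
  # loading vector itself always concentrates on high-variance bins, so
  # the eigenvalue, not the raw weights, carries the signal-vs-noise
  # distinction)
  nullcoh <- generate_cohort(
    cohort_spec(n_per_arm = c(A = 11, B = 11), bin_noise_cv = 0.05),
    seed = 12
  )
  xy0 <- cohort_xy(nullcoh)
  fit0 <- fit_pcaca_knn(xy0$x, xy0$labels, n_pc = 2, k = 5)
  expect_gt(fit$ca_eigenvalues[1], 10 * fit0$ca_eigenvalues[1])
  ratio_spiked <- mean(abs(la$weight[spiked])) / mean(abs(la$weight[!spiked]))
  expect_gt(ratio_spiked, 5)
})

test_that("tidiers expose the model in tabular form", {
  sep <- separable_clouds(n_per = 10, p = 4, gap = 6, seed = 5)
  fit <- fit_pcaca_knn(sep$x, sep$labels, n_pc = 2, k = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_named(td, c("feature", "center", "weight"))
  gl <- glance(fit)
  expect_equal(gl$n, 20)
  expect_equal(gl$n_pc, 2)
  expect_equal(gl$k, 3)
})
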