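test_that("Cliff's delta matches brute-force pair counts and magnitude labels", {
  expect_equal(cliffs_delta(1:5, 1:5)$delta, 0)
  expect_equal(cliffs_delta(1:5, 1:5)$magnitude, "negligible")

  all_above <- cliffs_delta(4:6, 1:3)
  expect_equal(all_above$delta, 1)
  expect_equal(all_above$magnitude, "large")

  cd <- cliffs_delta(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cd$delta, (1 - 6) / 9)
  expect_equal(cd$magnitude, "large")

  expect_equal(delta_magnitude(c(0.1, 0.2, 0.4, 0.6)),
               c("negligible", "small", "medium", "large"))
  expect_error(cliffs_delta(numeric(0), 1:3), "non-empty")
})

test_that("AUROC is the normalized Mann-Whitney statistic", {
  expect_equal(auroc(c(1, 2, 10, 20), c(0, 0, 1, 1), positive = 1), 1)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1),
               0.75)
  expect_equal(auroc(rep(3, 8), rep(c(0, 1), 4), positive = 1), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "two classes")
})

test_that("|delta| = |2 AUROC - 1| holds on random draws", {
  set.seed(10)
  for (i in 1:50) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- sample(1:8, n1, replace = TRUE)  # ties on purpose
    y <- sample(1:8, n2, replace = TRUE)
    d <- cliffs_delta(x, y)$delta
    a <- auroc(c(x, y), rep(c(1, 0), c(n1, n2)), positive = 1)
    expect_equal(abs(d), abs(2 * a - 1), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with full enumeration on small samples", {
  # golden small case: x below y entirely
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)

  # identical samples: no evidence either way
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # symmetry under swapping group names
  set.seed(11)
  x <- rnorm(6); y <- rnorm(5)
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)

  # enumeration oracle over every shape with n1 + n2 <= 8
  set.seed(12)
  for (n1 in 1:6) for (n2 in 1:(8 - n1)) {
    for (rep in 1:3) {
      x <- rnorm(n1); y <- rnorm(n2)   # continuous: untied a.s.
      expect_equal(mann_whitney(x, y)$p_value, enumerate_mw_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone along the sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("Youden threshold maximizes sensitivity + specificity", {
  bt <- best_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)
  expect_equal(bt$threshold, 2.5)
  expect_equal(bt$sensitivity, 1)
  expect_equal(bt$specificity, 1)

  sepd <- best_threshold(c(rnorm(10), rnorm(10) + 100),
                         rep(c(0, 1), each = 10), positive = 1)
  expect_equal(sepd$youden_j, 1)

  inter <- best_threshold(1:8, rep(c(0, 1), 4), positive = 1)
  expect_lt(inter$youden_j, 0.3)
  expect_error(best_threshold(1:4, rep(1, 4)), "two classes")
})

test_that("Pearson correlation and its t-test behave", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  p <- pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  ct <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(p$p_value, ct$p.value)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("screen_markers ranks the planted analyte effects", {
  coh <- generate_cohort(default_cohort_spec(), seed = 21)
  erp <- coh$meta$sample_id[coh$meta$er_status == "ER+"]
  feats <- coh$analytes[coh$analytes$sample_id %in% erp, ]
  stats <- screen_markers(feats, coh$meta, "response", positive = "GR")

  expect_named(stats, c("feature", "n1", "n2", "u_statistic", "p_value",
                        "q_value", "cliffs_delta", "delta_magnitude",
                        "auroc"))
  # planted effects: valine lower in complete responders (negative delta,
  # AUROC < 0.5), TNF-alpha higher (positive delta)
  val <- stats[stats$feature == "valine", ]
  tnf <- stats[stats$feature == "TNFa", ]
  expect_lt(val$cliffs_delta, 0)
  expect_lt(val$auroc, 0.5)
  expect_gt(tnf$cliffs_delta, 0)
  expect_true(all(stats$q_value >= stats$p_value - 1e-12, na.rm = TRUE))
  # the two planted markers sit at the top of the ranking
  expect_true(all(c("valine", "TNFa") %in% stats$feature[1:4]))

  # missingness reduces per-feature n in the other arm
  ern <- coh$meta$sample_id[coh$meta$er_status == "ER-"]
  stats_arm <- screen_markers(coh$analytes, coh$meta, "er_status",
                              positive = "ER+")
  tnf_arm <- stats_arm[stats_arm$feature == "TNFa", ]
  expect_lt(tnf_arm$n2, length(ern))
  expect_equal(tnf_arm$n1, length(erp))

  # permutation of sample order leaves every statistic unchanged
  set.seed(22)
  perm <- sample(nrow(feats))
  stats_perm <- screen_markers(feats[perm, ], coh$meta, "response", "GR")
  expect_equal(stats_perm, stats)
})
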