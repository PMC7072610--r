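make_two_feature_data <- function(n_per = 30, d1 = 2.5, d2 = 0, seed = 1) {
  set.seed(seed)
  lab <- rep(c("neg", "pos"), each = n_per)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(2 * n_per)),
    f1 = rnorm(2 * n_per) + ifelse(lab == "pos", d1, 0),
    f2 = rnorm(2 * n_per) + ifelse(lab == "pos", d2, 0),
    outcome = lab
  )
}

test_that("grid fusion puts the weight on the informative feature", {
  dat <- make_two_feature_data(d1 = 6, d2 = 0, seed = 1)
  m <- fit_linear_combo(dat, c("f1", "f2"), "outcome", "pos")
  expect_gt(m$weights[1], 0.85)
  expect_equal(sum(abs(m$weights)), 1)

  # symmetric equal-signal features share the weight
  dat2 <- make_two_feature_data(d1 = 2, d2 = 2, seed = 2)
  m2 <- fit_linear_combo(dat2, c("f1", "f2"), "outcome", "pos")
  expect_equal(unname(m2$weights[1]), 0.5, tolerance = 0.12)

  dat3 <- dat
  dat3$f2 <- 1
  expect_error(fit_linear_combo(dat3, c("f1", "f2"), "outcome", "pos"),
               "zero variance")
})

test_that("fusion invariants: weight normalization, AUROC dominance, affine invariance", {
  for (seed in 1:4) {
    dat <- make_two_feature_data(d1 = runif(1, 0.5, 2), d2 = runif(1, 0, 1.5),
                                 seed = 100 + seed)
    for (method in c("grid", "lda")) {
      m <- fit_linear_combo(dat, c("f1", "f2"), "outcome", "pos",
                            method = method)
      expect_equal(sum(abs(m$weights)), 1, tolerance = 1e-12)
    }
    m <- fit_linear_combo(dat, c("f1", "f2"), "outcome", "pos")
    a1 <- auroc(dat$f1, dat$outcome, positive = "pos")
    a2 <- auroc(dat$f2, dat$outcome, positive = "pos")
    single_best <- max(a1, 1 - a1, a2, 1 - a2)  # either orientation
    expect_gte(m$auroc, single_best - 1e-9)

    # affine rescaling of a raw feature is absorbed by standardization
    dat_scaled <- dat
    dat_scaled$f1 <- 1000 * dat_scaled$f1 - 7
    m_s <- fit_linear_combo(dat_scaled, c("f1", "f2"), "outcome", "pos")
    expect_equal(score_linear_combo(m_s, dat_scaled)$score,
                 score_linear_combo(m, dat)$score, tolerance = 1e-9)
  }
})

test_that("scoring applies training standardization and propagates missing", {
  dat <- make_two_feature_data(d1 = 4, d2 = 0, seed = 3)
  m <- fit_linear_combo(dat, c("f1", "f2"), "outcome", "pos")
  if (m$weights[1] == 1) {
    z1 <- (dat$f1 - m$center[1]) / m$scale[1] * m$sign[1]
    expect_equal(score_linear_combo(m, dat)$score, z1)
  }
  # both features at the training means give score zero
  centered <- tibble::tibble(f1 = m$center[1], f2 = m$center[2])
  expect_equal(score_linear_combo(m, centered)$score, 0)

  dat$f1[5] <- NA
  expect_message(sc <- score_linear_combo(m, dat), "missing")
  expect_true(is.na(sc$score[5]) && is.na(sc$pred[5]))
  expect_false(anyNA(sc$score[-5]))
})

test_that("logic-OR obeys its truth table and inherits sensitivity", {
  expect_equal(logic_or_predict(c(FALSE, TRUE, FALSE, TRUE),
                                c(FALSE, FALSE, TRUE, TRUE)),
               c(FALSE, TRUE, TRUE, TRUE))
  b <- c(TRUE, FALSE, TRUE)
  expect_equal(logic_or_predict(rep(FALSE, 3), b), b)
  expect_equal(logic_or_predict(b, b), b)
  expect_message(logic_or_predict(c(TRUE, NA), c(FALSE, FALSE)), "missing")

  a_tbl <- tibble::tibble(sample_id = c("s1", "s2"), pred = c("yes", "no"))
  b_tbl <- tibble::tibble(sample_id = c("s2", "s3"), pred = c("yes", "no"))
  or <- logic_or_predict(a_tbl, b_tbl, positive = "yes")
  expect_equal(or$pred[or$sample_id == "s2"], "yes")
  expect_error(
    logic_or_predict(a_tbl,
                     tibble::tibble(sample_id = "zz", pred = "yes"),
                     positive = "yes"),
    "no sample ids"
  )

  # OR fusion never loses a detection but can only lose specificity
  set.seed(14)
  for (i in 1:10) {
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    pa <- truth & runif(30) > 0.4 | runif(30) < 0.2
    pb <- truth & runif(30) > 0.4 | runif(30) < 0.2
    or <- logic_or_predict(pa, pb)
    ca <- confusion(pa, truth, TRUE)
    cb <- confusion(pb, truth, TRUE)
    co <- confusion(or, truth, TRUE)
    expect_gte(co$sensitivity, max(ca$sensitivity, cb$sensitivity))
    expect_lte(co$specificity, min(ca$specificity, cb$specificity))
  }
})

test_that("confusion arithmetic reproduces the relapse-model summary", {
  # 22 subjects: 8 relapsers all detected, 1 of 14 disease-free miscalled
  pred <- rep(c("yes", "yes", "no"), c(8, 1, 13))
  truth <- rep(c("yes", "no"), c(8, 14))
  cs <- confusion(pred, truth, positive = "yes")
  expect_equal(cs$sensitivity, 1)
  expect_equal(round(100 * cs$specificity, 1), 92.9)
  expect_equal(round(100 * cs$accuracy, 1), 95.5)

  perfect <- confusion(truth, truth, positive = "yes")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  allpos <- confusion(rep("yes", 22), truth, positive = "yes")
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 8 / 22)
})

test_that("preset weights build usable models without refitting", {
  pw <- preset_fusion_weights()
  expect_equal(pw$weight_1 + pw$weight_2, c(1, 1))
  expect_equal(pw$feature_1, c("TNFa", "IL2"))

  dat <- make_two_feature_data(d1 = 3, d2 = 1, seed = 4)
  m <- preset_fusion_model(dat, c("f1", "f2"), weights = c(0.784, 0.216),
                           label = "outcome", positive = "pos")
  expect_equal(unname(m$weights), c(0.784, 0.216))
  expect_equal(m$method, "preset")
  expect_gt(m$auroc, 0.9)
})
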