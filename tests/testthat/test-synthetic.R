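test_that("the default cohort matches the study-like design", {
  spec <- default_cohort_spec()
  expect_equal(unname(spec$n_per_arm), c(21L, 22L))
  expect_equal(spec$missingness$fraction, 0.38)
  expect_equal(spec$missingness$level, "ER-")
  expect_true(any(spec$effect_regions$low == 1.23 &
                  spec$effect_regions$high == 1.37))
  expect_equal(unname(spec$response_counts), c(13L, 11L))
  expect_equal(unname(spec$relapse_counts), c(3L, 8L))

  coh <- generate_cohort(spec, seed = 1)
  tab <- table(coh$meta$er_status)
  expect_equal(unname(tab[c("ER-", "ER+")]), c(21L, 22L), ignore_attr = TRUE)
  expect_equal(sum(coh$meta$response == "GR"), 24)
  expect_equal(sum(coh$meta$relapse == "yes"), 11)
  expect_equal(ncol(coh$matrix) - 1L, 368)
  expect_false(is_normalized(coh$matrix))
  expect_true(all(as.matrix(coh$matrix[-1]) > 0))
})

test_that("generation is bitwise reproducible under a seed", {
  spec <- default_cohort_spec()
  c1 <- generate_cohort(spec, seed = 5)
  c2 <- generate_cohort(spec, seed = 5)
  expect_identical(c1$matrix, c2$matrix)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$analytes, c2$analytes)
  c3 <- generate_cohort(spec, seed = 6)
  expect_false(identical(c1$matrix, c3$matrix))
})

test_that("missingness and noise converge to their nominal levels", {
  spec <- cohort_spec(
    n_per_arm = c(A = 1000, B = 10),
    bin_noise_cv = 0.15,
    analytes = tibble::tibble(analyte = "TNFa", meanlog = log(5), sdlog = 0.6),
    missingness = tibble::tibble(analyte = "TNFa", var = "er_status",
                                 level = "A", fraction = 0.38)
  )
  coh <- generate_cohort(spec, seed = 8)
  frac <- mean(is.na(coh$analytes$TNFa[coh$meta$er_status == "A"]))
  # binomial 3-sigma band around 0.38 at n = 1000
  expect_lt(abs(frac - 0.38), 3 * sqrt(0.38 * 0.62 / 1000))

  # per-bin coefficient of variation of the log-normal noise
  x <- as.matrix(coh$matrix[coh$meta$er_status == "A", -1])
  cvs <- apply(x[, 1:30], 2, function(v) sd(v) / mean(v))
  expect_true(all(abs(cvs - 0.15) / 0.15 < 0.10))
})

test_that("a null cohort carries no class signal; a strong spike is separable", {
  nullcoh <- generate_cohort(
    cohort_spec(n_per_arm = c(A = 20, B = 20), bin_noise_cv = 0.15),
    seed = 9
  )
  xy <- cohort_xy(nullcoh)
  acc <- loocv(xy$x, xy$labels, n_pc = 3, k = 5)$accuracy
  expect_lt(acc, 0.75)   # no better than noise-level fluctuation

  spiked <- generate_cohort(spiked_spec(fold = 3, cv = 0.05), seed = 10)
  xys <- cohort_xy(spiked)
  expect_equal(loocv(xys$x, xys$labels, n_pc = 2, k = 5)$accuracy, 1)
})

test_that("stronger spikes never make the classifier worse", {
  folds <- c(1, 1.3, 2)
  mean_acc <- vapply(folds, function(f) {
    mean(vapply(1:8, function(s) {
      coh <- generate_cohort(spiked_spec(fold = f, n_per = 8, cv = 0.15),
                             seed = 100 + s)
      xy <- cohort_xy(coh)
      loocv(xy$x, xy$labels, n_pc = 2, k = 3)$accuracy
    }, numeric(1)))
  }, numeric(1))
  # monotone within simulation error
  expect_true(all(diff(mean_acc) > -0.05))
  expect_gt(mean_acc[3], mean_acc[1])
})

test_that("logistic outcomes are driven by the designated analytes", {
  spec <- cohort_spec(
    n_per_arm = c(A = 150, B = 150),
    analytes = tibble::tibble(analyte = c("IL2", "IL10"),
                              meanlog = log(c(4, 3)), sdlog = c(0.6, 0.6)),
    outcome = "logistic",
    outcome_model = list(relapse = c("(Intercept)" = -0.5, IL2 = -2))
  )
  coh <- generate_cohort(spec, seed = 13)
  expect_true(all(c("relapse") %in% names(coh$meta)))
  il2 <- log(coh$analytes$IL2)
  expect_lt(mean(il2[coh$meta$relapse == "yes"]),
            mean(il2[coh$meta$relapse == "no"]))
})

test_that("cohorts round-trip losslessly through the text bundle", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(default_cohort_spec(), seed = 14)
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("matrix.csv", "meta.csv",
                                               "analytes.csv", "truth.json")))))
  suppressMessages({
    mat <- read_feature_table(file.path(dir, "matrix.csv"))
    ana <- read_feature_table(file.path(dir, "analytes.csv"))
  })
  expect_equal(as.matrix(mat[-1]), as.matrix(coh$matrix[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(is.na(ana$TNFa), is.na(coh$analytes$TNFa))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 14)
  expect_equal(unlist(truth$n_per_arm), c("ER-" = 21L, "ER+" = 22L))
})

test_that("spec validation rejects inconsistent designs", {
  expect_error(cohort_spec(n_per_arm = c(A = 2, B = 10)), ">= 4")
  expect_error(cohort_spec(n_per_arm = c(10, 10)), "named")
  expect_error(
    cohort_spec(n_per_arm = c(A = 10, B = 10),
                effect_regions = tibble::tibble(low = 12, high = 13, fold = 2,
                                                var = "er_status", level = "B",
                                                within_var = NA,
                                                within_level = NA)),
    "outside"
  )
  expect_error(
    cohort_spec(n_per_arm = c(A = 10, B = 10),
                response_counts = c(A = 11)),
    "exceed"
  )
})
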