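# Shared fixture builders: everything is generated in code at test time.

# Two Gaussian clouds separated by `gap` pooled SDs in every feature.
separable_clouds <- function(n_per = 20, p = 10, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = gap), n_per))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

# Pure-noise features with balanced labels carrying no signal.
null_clouds <- function(n_per = 10, p = 20, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(2 * n_per * p), 2 * n_per),
       labels = sample(rep(c("a", "b"), n_per)))
}

# A small two-arm cohort spec with a single spiked spectral window.
spiked_spec <- function(fold, n_per = 11, low = 1.23, high = 1.37,
                        cv = 0.05) {
  cohort_spec(
    n_per_arm = c("A" = n_per, "B" = n_per),
    bin_noise_cv = cv,
    effect_regions = tibble::tibble(
      low = low, high = high, fold = fold,
      var = "er_status", level = "B",
      within_var = NA, within_level = NA
    )
  )
}

# Normalized feature matrix + labels from a synthetic cohort.
cohort_xy <- function(coh) {
  norm <- total_integral_normalize(coh$matrix)
  list(x = as.matrix(norm[setdiff(names(norm), "sample_id")]),
       labels = coh$meta$er_status)
}

# Brute-force two-sided Mann-Whitney p by full enumeration of label
# assignments (oracle; independent of wilcox.test).
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  combs <- utils::combn(n, n1)
  u_null <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  u_obs <- u_of(x, y)
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Hand step-up BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}
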