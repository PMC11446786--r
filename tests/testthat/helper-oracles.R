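# Independent oracles used across the suite. These reimplement the target
# quantities by brute force (grids, enumeration, direct arithmetic) and are
# deliberately kept free of the package's own fitting code.

# Beta-binomial log-likelihood written out directly.
oracle_bb_loglik <- function(i, n, theta, rho) {
  if (rho <= 1e-6) return(sum(dbinom(i, n, theta, log = TRUE)))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  sum(lchoose(n, i) + lbeta(i + a, n - i + b) - lbeta(a, b))
}

# Beta-binomial log-likelihood profile over a vector of candidate means:
# samples enter as an explicit sum, candidates vectorized.
oracle_bb_profile <- function(i, n, thetas, rho) {
  if (rho <= 1e-6) {
    ll <- rep(0, length(thetas))
    for (j in seq_along(i)) {
      ll <- ll + dbinom(i[j], n[j], thetas, log = TRUE)
    }
    return(ll)
  }
  a <- thetas * (1 - rho) / rho
  b <- (1 - thetas) * (1 - rho) / rho
  ll <- rep(0, length(thetas))
  for (j in seq_along(i)) {
    ll <- ll + lchoose(n[j], i[j]) + lbeta(i[j] + a, n[j] - i[j] + b) -
      lbeta(a, b)
  }
  ll
}

# Brute-force LRT statistic: psi grid with step `step`, coarse log-spaced rho
# grid shared by both hypotheses. Groups maximize independently given rho.
oracle_lrt_stat <- function(i_a, n_a, i_b, n_b, step = 1e-4) {
  thetas <- seq(step, 1 - step, by = step)
  coarse <- c(1e-6, exp(seq(log(1e-4), log(0.9), length.out = 50)))
  # profile log-likelihood in rho (theta maximized on the grid); H1 shares
  # one rho across both groups, as in the model under test
  ll1_at <- function(r) {
    max(oracle_bb_profile(i_a, n_a, thetas, r)) +
      max(oracle_bb_profile(i_b, n_b, thetas, r))
  }
  ll0_at <- function(r) max(oracle_bb_profile(c(i_a, i_b), c(n_a, n_b),
                                              thetas, r))
  max_over_rho <- function(ll_at) {
    ll <- vapply(coarse, ll_at, numeric(1))
    r_best <- coarse[which.max(ll)]
    fine <- exp(seq(log(max(r_best / 4, 1e-7)), log(min(r_best * 4, 0.9)),
                    length.out = 60))
    max(max(ll), max(vapply(fine, ll_at, numeric(1))))
  }
  2 * (max_over_rho(ll1_at) - max_over_rho(ll0_at))
}

# Exhaustive upper-tail hypergeometric probability by direct enumeration of
# overlap counts, using only factorials.
oracle_hyper_greater <- function(n_a, n_b, k, N) {
  choose2 <- function(n, r) exp(lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1))
  support <- max(0, n_a + n_b - N):min(n_a, n_b)
  probs <- vapply(support, function(x) {
    choose2(n_a, x) * choose2(N - n_a, n_b - x) / choose2(N, n_b)
  }, numeric(1))
  sum(probs[support >= k])
}

# One-way ANOVA F by direct sum-of-squares decomposition.
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Tiny deterministic two-group count table for interface tests.
toy_counts <- function() {
  tibble::tibble(
    event_id = rep(c("e1", "e2"), each = 8),
    gene = rep(c("gA", "gB"), each = 8),
    sample_id = rep(sprintf("s%d", 1:8), times = 2),
    group = rep(rep(c("CON", "BMT"), each = 4), times = 2),
    inclusion = c(30, 28, 35, 31, 55, 60, 52, 58,
                  12, 15, 11, 14, 13, 12, 16, 12),
    skipping = c(70, 72, 65, 69, 45, 40, 48, 42,
                 88, 85, 89, 86, 87, 88, 84, 88),
    inc_form_len = 1, skip_form_len = 1)
}
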