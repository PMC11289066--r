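test_that("one-sample t matches a textbook hand computation and the d definition", {
  x <- c(0.6, 0.7, 0.5, 0.8, 0.6)
  r <- one_sample_t(x, mu0 = 0.5)
  m <- mean(x); s <- sd(x); n <- 5
  t_hand <- (m - 0.5) / (s / sqrt(n))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, pt(t_hand, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$d, (m - 0.5) / s, tolerance = 1e-12)
  expect_lt(r$d_ci_lower, r$d)

  # mean equal to mu0 -> t = 0, one-sided p = 0.5
  y <- c(0.4, 0.5, 0.6)
  r0 <- one_sample_t(y, mu0 = 0.5)
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 0.5, tolerance = 1e-12)

  expect_error(one_sample_t(rep(0.7, 5), 0.5), "degenerate")
})

test_that("t and p agree with the reference implementation on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n, 0.03, 1)
    alt <- sample(c("greater", "less", "two.sided"), 1)
    r <- one_sample_t(x, mu0 = 0, alternative = alt)
    ref <- t.test(x, mu = 0, alternative = alt)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired t reduces exactly to a one-sample t on the differences", {
  set.seed(7)
  a <- rnorm(15, 0.6, 0.1)
  b <- rnorm(15, 0.5, 0.1)
  rp <- paired_t(a, b)
  r1 <- one_sample_t(a - b, mu0 = 0)
  expect_equal(rp[c("t", "df", "p", "d", "d_ci_lower", "bf10")],
               r1[c("t", "df", "p", "d", "d_ci_lower", "bf10")])
  expect_equal(paired_t(a, a + 0, alternative = "greater")$t, 0)
  expect_error(paired_t(a, b[-1]), "equal length")
  expect_error(paired_t(a, a + 1), "degenerate")
})

test_that("d lower bound: definition, ordering, and one-sided coverage", {
  # definition: noncentral-t CDF at the observed t equals the level
  lb <- cohens_d_ci_lower(3.0, 30)
  expect_equal(suppressWarnings(pt(3.0, 29, lb * sqrt(30))), 0.95,
               tolerance = 1e-6)
  # bound below the point estimate; negative when d = 0
  expect_lt(cohens_d_ci_lower(0, 100), 0)
  expect_lt(lb, 3.0 / sqrt(30))

  # Monte-Carlo one-sided coverage at n = 30, true d = 0.5
  set.seed(11)
  n <- 30; d_true <- 0.5; reps <- 2000
  covered <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n, d_true, 1)
    tt <- sqrt(n) * mean(x) / sd(x)
    cohens_d_ci_lower(tt, n) <= d_true
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("JZS Bayes factor matches an independent fine-quadrature oracle", {
  for (tt in c(0, 0.8, 2.5, 4.0, 7.58)) {
    for (n in c(10, 45, 136)) {
      expect_equal(jzs_bf(tt, n, alternative = "two.sided"),
                   jzs_bf_oracle(tt, n),
                   tolerance = 1e-4)
    }
  }
})

test_that("JZS Bayes factor: evidence direction, monotonicity, mixture identity, prior collapse", {
  # t = 0 favors the null
  expect_lt(jzs_bf(0, 50, alternative = "two.sided"), 1)
  # strictly increasing in |t| at fixed n
  grid <- seq(0, 6, by = 0.5)
  bfs <- vapply(grid, jzs_bf, 0, n = 40, alternative = "two.sided")
  expect_true(all(diff(bfs) > 0))
  # two-sided is the equal mixture of the two one-sided variants
  for (tt in c(-2.3, 1.1, 3.7)) {
    expect_equal(
      jzs_bf(tt, 25, alternative = "two.sided"),
      (jzs_bf(tt, 25, alternative = "greater") +
         jzs_bf(tt, 25, alternative = "less")) / 2,
      tolerance = 1e-8)
  }
  # prior scale -> 0 collapses the alternative onto the null: BF -> 1
  # (the approach is linear in the scale, so assert monotone convergence)
  gap <- vapply(c(0.1, 0.01, 1e-4),
                function(s) abs(jzs_bf(2.5, 40, scale = s,
                                       alternative = "two.sided") - 1), 0)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("one-sided binomial test equals the brute-force tail sum", {
  expect_equal(binomial_test_one_sided(60, 100, 0.5),
               sum(dbinom(60:100, 100, 0.5)), tolerance = 1e-12)
  expect_equal(binomial_test_one_sided(10, 10, 0.4), 0.4^10)
  expect_equal(binomial_test_one_sided(0, 17), 1)
})

test_that("t power solver reproduces the preregistered sample sizes and is monotone", {
  expect_equal(power_t_one_sample(0.61, alpha = 0.05, power = 0.90), 25L)
  expect_equal(power_t_one_sample(1.47, alpha = 0.05, power = 0.90), 6L)
  pow <- function(n, d) pt(qt(0.95, n - 1), n - 1, ncp = d * sqrt(n),
                           lower.tail = FALSE)
  expect_true(all(diff(vapply(5:60, pow, 0, d = 0.61)) > 0))
  # the returned n is minimal
  expect_lt(pow(24, 0.61), 0.90)
  expect_gte(pow(25, 0.61), 0.90)
})

test_that("exact binomial power solver agrees with brute-force search; normal variant reproduces 119", {
  # brute-force oracle over n for a large effect
  brute <- function(g, alpha = 0.05, power = 0.90) {
    for (n in 1:200) {
      k <- which(pbinom(0:n - 1, n, 0.5, lower.tail = FALSE) <= alpha)[1] - 1
      if (is.na(k)) next
      if (pbinom(k - 1, n, 0.5 + g, lower.tail = FALSE) >= power) return(n)
    }
    NA_integer_
  }
  expect_equal(power_binomial_one_sided(0.49), brute(0.49))
  expect_lte(power_binomial_one_sided(0.49), 10L)
  expect_equal(power_binomial_one_sided(0.2), brute(0.2))
  # the two documented conventions for g = 0.13
  expect_equal(power_binomial_one_sided(0.13), 128L)
  expect_equal(power_binomial_one_sided(0.13, method = "normal"), 119L)
  # n_min nonincreasing in g
  ns <- vapply(c(0.10, 0.15, 0.20, 0.30, 0.45),
               power_binomial_one_sided, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("simulated power at the solved n meets the target", {
  set.seed(5)
  n <- power_t_one_sample(0.8, alpha = 0.05, power = 0.80)
  rej <- mean(vapply(1:2000, function(i) {
    x <- rnorm(n, 0.8, 1)
    one_sample_t(x, mu0 = 0, alternative = "greater")$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.80 - 3 * sqrt(0.8 * 0.2 / 2000))
})

test_that("sequential stopping rule fires at the first threshold crossing", {
  expect_equal(sequential_bf_stop(18.16)$decision, "stop_H1")
  expect_equal(sequential_bf_stop(18.16)$n_used, 50)
  r <- sequential_bf_stop(c(0.3, 0.15))
  expect_equal(r$decision, "stop_H0")
  expect_equal(r$batch, 2)
  expect_equal(r$n_used, 75)
  r2 <- sequential_bf_stop(c(1, 1, 1, 1, 1), batch_sizes = c(50, 25),
                           n_max = 150)
  expect_equal(r2$decision, "cap_reached")
  expect_equal(r2$n_used, 150)
  expect_equal(sequential_bf_stop(c(2, 3), n_max = 500)$decision, "continue")
})

test_that("Pearson correlation matches a hand computation", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 5, 4, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  r <- pearson_r(x, y)
  expect_equal(r$r, r_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("Bonferroni threshold and flags agree with p.adjust", {
  b <- bonferroni(c(0.009, 0.02, 0.2, 0.5, 0.04), alpha = 0.05)
  expect_equal(b$threshold, 0.01)
  expect_equal(b$significant,
               stats::p.adjust(c(0.009, 0.02, 0.2, 0.5, 0.04),
                               "bonferroni") < 0.05)
  expect_equal(bonferroni(0.03)$threshold, 0.05)
})

test_that("group Bayes factors echo reported webcam-study magnitudes from their t statistics", {
  # rounded t inputs, so compared loosely; sanity anchors, not oracles
  expect_equal(jzs_bf(3.06, 45), 18.16, tolerance = 0.02)
  expect_equal(jzs_bf(7.58, 136), 3.10e9, tolerance = 0.02)
  expect_equal(jzs_bf(3.58, 32), 56.75, tolerance = 0.02)
})
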