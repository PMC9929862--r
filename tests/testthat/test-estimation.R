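# Estimation statistics.

test_that("bootstrap mean difference has exact point estimates", {
  r0 <- bootstrap_mean_difference(c(1, 2, 3), c(1, 2, 3), n_boot = 2000,
                                  seed = 1)
  expect_equal(r0$mean_diff, 0)
  expect_true(r0$ci_low <= 0 && r0$ci_high >= 0)
  r3 <- bootstrap_mean_difference(c(1, 2, 3), c(4, 5, 6), n_boot = 2000,
                                  seed = 1)
  expect_equal(r3$mean_diff, 3)
})

test_that("bootstrap handles degenerate constant groups", {
  r <- bootstrap_mean_difference(rep(1, 5), rep(4, 5), n_boot = 500, seed = 1)
  expect_true(r$degenerate)
  expect_equal(c(r$ci_low, r$ci_high), c(3, 3))
})

test_that("bootstrap is reproducible by seed and validates inputs", {
  a <- rnorm(10); b <- rnorm(10)
  r1 <- bootstrap_mean_difference(a, b, n_boot = 500, seed = 5)
  r2 <- bootstrap_mean_difference(a, b, n_boot = 500, seed = 5)
  expect_identical(r1$boot_distribution, r2$boot_distribution)
  expect_error(bootstrap_mean_difference(1:2, 1:5), "n >= 3")
  expect_error(bootstrap_mean_difference(1:5, 1:4, paired = TRUE), "align")
})

test_that("CI width shrinks roughly as n^(-1/2)", {
  set.seed(6)
  width <- function(n) {
    mean(vapply(1:60, function(k) {
      r <- bootstrap_mean_difference(rnorm(n), rnorm(n), n_boot = 400,
                                     seed = k)
      r$ci_high - r$ci_low
    }, numeric(1)))
  }
  ratio <- width(20) / width(40)
  expect_lt(abs(ratio - sqrt(2)), 0.15 * sqrt(2))  # doubling n halves width
})

test_that("BCa reduces to the percentile interval for symmetric inputs", {
  a <- c(-3, -1, 0, 1, 3, -2, 2)
  b <- a + 1
  r <- bootstrap_mean_difference(a, b, n_boot = 20000, seed = 7)
  q <- quantile(r$boot_distribution, c(0.025, 0.975), names = FALSE)
  w <- q[2] - q[1]
  expect_lt(abs(r$ci_low - q[1]), 0.15 * w)
  expect_lt(abs(r$ci_high - q[2]), 0.15 * w)
})

test_that("permutation test is exact on the enumeration path", {
  r <- permutation_test(c(1, 2), c(10, 11))
  expect_true(r$exhaustive)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$n_perm_used, 6)
  same <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
})

test_that("permutation p is invariant to group-label swap", {
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(permutation_test(a, b)$p, permutation_test(b, a)$p)
})

test_that("Monte-Carlo path never returns zero and is seeded", {
  a <- rnorm(15); b <- rnorm(15) + 10
  r <- permutation_test(a, b, n_perm = 200, seed = 1)
  expect_false(r$exhaustive)
  expect_equal(r$p, 1 / 201)
  expect_equal(permutation_test(a, b, n_perm = 200, seed = 1)$p, r$p)
})

test_that("pearson correlation endpoints and degeneracy", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_true(is.na(pearson_correlation(rep(1, 5), rnorm(5))$r))
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("pearson r is unbiased at rho = 0.6", {
  set.seed(8)
  rs <- vapply(1:500, function(k) {
    x <- rnorm(200)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(200)
    pearson_correlation(x, y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.02)
})

test_that("slope comparison endpoints", {
  x <- 1:10
  same <- compare_slopes_lr(x, 2 * x + rnorm(10, 0, 0.001),
                            x, 2 * x + rnorm(10, 0, 0.001))
  expect_gt(same$lr_p, 0.05)
  perfect <- compare_slopes_lr(x, x, x, -x)
  expect_lt(perfect$lr_p, 1e-6)
  both_line <- compare_slopes_lr(x, 2 * x, x, 2 * x)
  expect_equal(both_line$lr_statistic, 0)
  expect_error(compare_slopes_lr(rep(1, 5), rnorm(5), 1:5, rnorm(5)),
               "degenerate")
})

test_that("per-group regression table is reported", {
  set.seed(9)
  x <- rnorm(20)
  cmp <- compare_slopes_lr(x, 2 + 3 * x + rnorm(20, 0, 0.01),
                           x, 1 - 2 * x + rnorm(20, 0, 0.01))
  expect_equal(cmp$per_group$slope, c(3, -2), tolerance = 0.01)
  expect_equal(cmp$per_group$intercept, c(2, 1), tolerance = 0.01)
})

test_that("wilcoxon against chance: symmetry, exact small-n, guards", {
  sym <- wilcoxon_vs_chance(c(0.4, 0.6, 0.3, 0.7), min_n = 4)
  expect_equal(sym$p, 1)
  r <- wilcoxon_vs_chance(c(0.6, 0.7, 0.8), alternative = "greater",
                          min_n = 3)
  expect_equal(r$p, 1 / 8)
  allties <- wilcoxon_vs_chance(rep(0.5, 6))
  expect_true(is.na(allties$p))
  expect_error(wilcoxon_vs_chance(c(0.6, 0.7)), "at least")
})

test_that("wilcoxon type-I error is calibrated at n = 20", {
  # The exact signed-rank test is discrete, so its true size at nominal 0.05
  # is the largest achievable level below it: P(p < 0.05) under H0, computed
  # from the signed-rank null distribution. Compare the simulated rejection
  # rate against that size within 3 Monte-Carlo standard errors.
  n <- 20
  w <- 0:(n * (n + 1) / 2)
  pv <- vapply(w, function(k) {
    min(1, 2 * min(psignrank(k, n), 1 - psignrank(k - 1, n)))
  }, numeric(1))
  size <- sum(dsignrank(w, n)[pv < 0.05])
  set.seed(10)
  rej <- vapply(1:2000, function(k) {
    wilcoxon_vs_chance(runif(20, 0.3, 0.7))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - size), 3 * sqrt(size * (1 - size) / 2000))
})
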