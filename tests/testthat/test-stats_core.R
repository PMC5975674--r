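test_that("BH adjustment matches the hand-evaluated step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone: larger p never gets smaller q
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # re-adjusting never un-discovers anything (q'' >= q'), and ties in the
  # adjusted values are preserved
  q2 <- bh_adjust(q)
  expect_true(all(q2 >= q - 1e-12))
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("BH controls the chance of any discovery under the global null", {
  set.seed(3)
  any_hit <- replicate(500, {
    q <- bh_adjust(runif(1000))
    any(q < 0.05)
  })
  # FWER under the global null equals FDR <= 0.05; allow 2 MC SEs
  expect_lt(mean(any_hit), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("OLS coefficient test reproduces the closed-form toy", {
  r <- ols_coef_test(c(1, 2, 3, 4), cbind(1, c(0, 0, 1, 1)), 2)
  expect_equal(r$estimate, 2)
  expect_equal(r$se, sqrt(0.5), tolerance = 1e-9)
  expect_equal(r$statistic, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(2), 2), tolerance = 1e-12)
})

test_that("OLS test is calibrated under the null and degenerate fits give p = 1", {
  set.seed(5)
  n <- 40
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  Y <- matrix(rnorm(2000 * n), 2000, n)
  p <- handprint:::.ols_rows(Y, X, 2L)$p
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # response equal to a covariate already in the design: testing the other
  # coefficient returns 0 with p = 1
  y <- X[, 3]
  r <- ols_coef_test(y, X, 2L)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(ols_coef_test(rnorm(10), cbind(1, 1:10, 2 * (1:10)), 2),
               "rank-deficient")
})

test_that("Kaplan-Meier matches the product-limit by hand and is monotone", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  kmc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))
  set.seed(6)
  km2 <- km_estimate(rexp(50), rbinom(50, 1, 0.7))
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("log-rank equals an independent brute-force O/E tally and is label-invariant", {
  set.seed(8)
  time <- c(rexp(20, 1), rexp(20, 2))
  event <- rbinom(40, 1, 0.8)
  group <- rep(c("a", "b"), each = 20)
  r <- log_rank_test(time, event, group)
  expect_equal(r$statistic, brute_logrank_2g(time, event, group),
               tolerance = 1e-10)
  r2 <- log_rank_test(time, event, ifelse(group == "a", "z", "y"))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
  # duplicated groups: exchangeable, statistic 0
  r3 <- log_rank_test(rep(time, 2), rep(event, 2), rep(c("g1", "g2"),
                                                       each = 40))
  expect_equal(r3$statistic, 0, tolerance = 1e-9)
  expect_equal(r3$p, 1, tolerance = 1e-9)
  expect_warning(r4 <- log_rank_test(c(1, 2, 3, 4), rep(0, 4),
                                     c("a", "a", "b", "b")), "no events")
  expect_equal(r4$p, 1)
})

test_that("Kruskal-Wallis matches the hand rank computation and a permutation oracle", {
  r <- kruskal_wallis(1:10, rep(c("a", "b"), each = 5))
  expect_equal(r$statistic, 6.818182, tolerance = 1e-6)
  expect_equal(r$p, 0.009, tolerance = 0.01)
  expect_equal(kruskal_wallis(rep(1:4, 3), rep(c("a", "b", "c"), 4))$statistic,
               0, tolerance = 1e-9)
  expect_warning(rt <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)), "tied")
  expect_equal(rt$p, 1)
  # 3-group toy: chi-square approximation close to the permutation p
  set.seed(9)
  vals <- c(rnorm(8), rnorm(8) + 1.2, rnorm(8) + 2.4)
  grp <- rep(c("a", "b", "c"), each = 8)
  obs <- kruskal_wallis(vals, grp)
  perm <- replicate(4000, kruskal_wallis(vals, sample(grp))$statistic)
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)
})

test_that("chi-square independence matches the shared 2x2 oracle and drops zero margins", {
  expect_equal(chi_square_independence(matrix(25, 2, 2))$p, 1)
  r <- chi_square_independence(matrix(c(9, 2, 1, 8), 2))
  expect_equal(r$statistic, 9.89899, tolerance = 1e-5)
  expect_warning(
    r2 <- chi_square_independence(rbind(c(9, 1), c(0, 0), c(2, 8))),
    "zero")
  expect_equal(r2$statistic, 9.89899, tolerance = 1e-5)
})

test_that("hypergeometric tail equals exact enumeration on the 20/5/5 toy", {
  expect_equal(hypergeom_tail(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  # enumeration oracle: P[X >= x] by summing the pmf
  enum <- function(x) sum(sapply(x:5, function(i)
    choose(5, i) * choose(15, 5 - i) / choose(20, 5)))
  for (x in 0:5)
    expect_equal(hypergeom_tail(x, 5, 5, 20), enum(x), tolerance = 1e-12)
  expect_error(hypergeom_tail(6, 5, 5, 20), "impossible")
})

test_that("Cohen's kappa is 0 for a random confusion and 1 for a perfect one", {
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohens_kappa(diag(c(10, 20))), 1)
})
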