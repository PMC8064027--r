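test_that("Crawford-Howell t matches the closed form and tail identities", {
  y <- c(1, 2, 3, 4, 5)
  r <- crawford_howell_t(y, 0)
  # oracle: direct formula + t CDF
  t_expect <- (0 - 3) / (sd(y) * sqrt(6 / 5))
  expect_equal(r$statistic, t_expect, tolerance = 1e-12)
  expect_equal(r$statistic, -1.732, tolerance = 1e-3)
  expect_identical(r$df, 4)
  expect_equal(r$p, pt(t_expect, 4), tolerance = 1e-12)
  expect_equal(r$p, 0.079, tolerance = 1e-2)
  # case at the control mean: t = 0, lower p = 0.5
  r0 <- crawford_howell_t(y, 3)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 0.5)
  # two-tailed p = 2 * min(lower, upper)
  set.seed(8)
  for (i in 1:5) {
    yy <- rnorm(12); ys <- rnorm(1, sd = 2)
    lo <- crawford_howell_t(yy, ys, "lower")$p
    up <- crawford_howell_t(yy, ys, "upper")$p
    two <- crawford_howell_t(yy, ys, "two")$p
    expect_equal(two, 2 * min(lo, up), tolerance = 1e-12)
  }
  expect_error(crawford_howell_t(c(1, 1, 1), 0), "constant")
  expect_error(crawford_howell_t(c(1, 2), 0), "at least 3")
})

test_that("btd_cov without covariates agrees with the analytic test", {
  set.seed(14)
  for (n in c(10, 46)) {
    y <- rnorm(n); y <- (y - mean(y)) / sd(y)
    for (z in c(-3, -1, 0)) {
      ch <- crawford_howell_t(y, z)
      b <- btd_cov(y, z, n_mc = 20000, seed = 99)
      expect_lt(abs(ch$p - b$p), 0.01)
    }
  }
})

test_that("btd_cov posterior behaves at the conditional mean and extremes", {
  set.seed(15)
  n <- 46
  age <- rnorm(n, 60, 12)
  y <- -0.03 * age + rnorm(n, 4, 0.8)
  fitb <- coef(lm(y ~ age))
  at_mean <- unname(fitb[1] + fitb[2] * 65)
  r <- btd_cov(y, at_mean, X = age, x_star = 65, n_mc = 20000, seed = 1)
  expect_gt(r$p, 0.45); expect_lt(r$p, 0.55)
  expect_true(r$ci[1] <= r$p && r$p <= r$ci[2])
  r2 <- btd_cov(y, at_mean - 10 * sd(y), X = age, x_star = 65,
                n_mc = 20000, seed = 1)
  expect_lt(r2$p, 0.001)
  expect_lt(r2$z_ccc, 0)
  expect_equal(r2$abnormality_pct, 100 * r2$p, tolerance = 1e-9)
})

test_that("btd_cov p is monotone decreasing in the case score at fixed seed", {
  set.seed(16)
  y <- rnorm(30)
  ps <- vapply(seq(-3, 3, by = 0.5),
               function(z) btd_cov(y, z, n_mc = 5000, seed = 7)$p, 0)
  expect_true(all(diff(ps) > 0))
})

test_that("btd_cov and bsdt_cov are deterministic given a seed", {
  set.seed(17)
  n <- 46
  age <- rnorm(n); Y <- matrix(rnorm(2 * n), n)
  b1 <- btd_cov(Y[, 1], -1.2, X = age, x_star = 0.3, n_mc = 5000, seed = 12)
  b2 <- btd_cov(Y[, 1], -1.2, X = age, x_star = 0.3, n_mc = 5000, seed = 12)
  expect_identical(b1[c("p", "ci", "abnormality_pct")],
                   b2[c("p", "ci", "abnormality_pct")])
  d1 <- bsdt_cov(Y, c(-2, 0), X = age, x_star = 0.3, n_mc = 5000, seed = 12)
  d2 <- bsdt_cov(Y, c(-2, 0), X = age, x_star = 0.3, n_mc = 5000, seed = 12)
  expect_identical(unclass(d1)[c("p_diff", "ci", "z_x", "z_y", "rho")],
                   unclass(d2)[c("p_diff", "ci", "z_x", "z_y", "rho")])
})

test_that("doubling the Monte-Carlo size shrinks the standard error of p", {
  set.seed(18)
  y <- rnorm(20)
  se_of <- function(nmc) {
    ps <- vapply(1:40, function(s)
      btd_cov(y, -1.5, n_mc = nmc, seed = 1000 + s)$p, 0)
    sd(ps)
  }
  s1 <- se_of(1000); s2 <- se_of(4000)
  # quadrupling n_mc should halve the SE (allow generous sampling slack)
  expect_lt(s2, 0.75 * s1)
})

test_that("bsdt_cov matches the large-n closed form with no correlation", {
  set.seed(19)
  n <- 4000
  Y <- matrix(rnorm(2 * n), n)          # rho = 0, unit variances
  ys <- c(mean(Y[, 1]) - 2 * sd(Y[, 1]), mean(Y[, 2]))
  r <- bsdt_cov(Y, ys, tail = "lower", n_mc = 40000, seed = 3)
  expect_lt(abs(r$p_diff - pnorm(-2 / sqrt(2))), 0.01)
})

test_that("bsdt_cov detects no difference for equal standardised deviations", {
  set.seed(20)
  n <- 46
  Y <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, .5, .5, 1), 2))
  z <- -1.4
  ys <- c(mean(Y[, 1]) + z * sd(Y[, 1]), mean(Y[, 2]) + z * sd(Y[, 2]))
  r <- bsdt_cov(Y, ys, n_mc = 20000, seed = 5)
  expect_gt(r$p_diff, 0.85)
})

test_that("single-case tests reject ill-posed designs", {
  set.seed(21)
  y <- rnorm(10); age <- rnorm(10)
  expect_error(btd_cov(y[1:3], 0, X = age[1:3], x_star = 0), "n > c")
  expect_error(btd_cov(y, 0, X = cbind(age, age), x_star = c(0, 0)),
               "collinear")
  expect_error(btd_cov(y, 0, X = rep(2, 10), x_star = 2), "zero variance")
  Y <- cbind(y, 2 * y)                  # rho = 1
  expect_error(bsdt_cov(Y, c(0, 0), n_mc = 2000, seed = 1), "unity")
  expect_error(bsdt_cov(cbind(y, rnorm(10)), c(0, 0), prior = "calibrated"),
               "not implemented")
})

test_that("pooled-variance t from summary statistics behaves", {
  r <- pooled_t_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_identical(r$df, 20)
  # equivalence with t.test on raw data for a constructed example
  set.seed(22)
  a <- rnorm(14, 3, 2); b <- rnorm(9, 4, 2)
  rt <- t.test(a, b, var.equal = TRUE)
  rs <- pooled_t_from_summary(mean(a), sd(a), 14, mean(b), sd(b), 9)
  expect_equal(rs$t, unname(rt$statistic), tolerance = 1e-10)
  expect_equal(rs$p, rt$p.value, tolerance = 1e-10)
  expect_error(pooled_t_from_summary(1, 0, 5, 2, 0, 5), "both")
  expect_error(pooled_t_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})
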