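test_that("KMO equals 0.5 for any bivariate correlation matrix", {
  for (r in c(-0.8, -0.3, 0.2, 0.64, 0.95)) {
    R <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo(R), 0.5, tolerance = 1e-12)
  }
})

test_that("KMO matches the direct-formula oracle and rejects degenerate R", {
  R <- matrix(0.64, 4, 4); diag(R) <- 1
  # independent evaluation straight from the definition
  Ri <- solve(R)
  Q <- -Ri / sqrt(outer(diag(Ri), diag(Ri)))
  off <- upper.tri(R)
  oracle <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  expect_equal(kmo(R), oracle, tolerance = 1e-10)
  expect_error(kmo(diag(4)), "off-diagonal")
  S <- matrix(1, 3, 3)          # singular
  expect_error(kmo(S), "singular")
  expect_error(kmo(matrix(c(1, .5, .4, 1), 2)), "symmetric")
})

test_that("component extraction follows the Kaiser rule with fallback", {
  # identity-correlation data: no eigenvalue exceeds 1, fall back to one
  set.seed(3)
  Z <- matrix(rnorm(500 * 3), 500)
  Z <- Z %*% solve(chol(cov(Z)))      # empirical correlation exactly I
  sol <- extract_components(Z)
  expect_identical(sol$n_retained, 1L)
  expect_equal(sum(sol$eigenvalues), 3, tolerance = 1e-8)
  # two perfectly correlated tests: one component explaining everything
  x <- rnorm(40)
  sol2 <- extract_components(cbind(a = x, b = 2 * x + 3))
  expect_identical(sol2$n_retained, 1L)
  expect_equal(sol2$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(sol2$total_var_explained, 1, tolerance = 1e-12)
  expect_error(extract_components(cbind(x, rep(1, 40))), "constant")
})

test_that("varimax preserves communalities and matches a grid-search oracle", {
  set.seed(17)
  for (rep in 1:3) {
    L0 <- matrix(rnorm(12, sd = 0.5), 6, 2)
    sol <- structure(list(R = diag(6), eigenvalues = rep(1, 6),
                          n_retained = 2L, loadings = L0, rotated = FALSE,
                          var_explained = c(0.5, 0.5),
                          total_var_explained = 1, kmo = 0.5),
                     class = "pca_solution")
    rot <- rotate_varimax(sol)
    # orthogonal rotation, communality conservation
    expect_lt(max(abs(crossprod(rot$rotmat) - diag(2))), 1e-8)
    expect_lt(max(abs(rowSums(rot$loadings^2) - rowSums(L0^2))), 1e-8)
    # 0.01-degree brute-force maximiser of the criterion
    angs <- seq(0, 90, by = 0.01) * pi / 180
    best <- max(vapply(angs, function(a) {
      Tm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
      caseseries:::varimax_criterion(L0 %*% Tm)
    }, 0))
    got <- caseseries:::varimax_criterion(rot$loadings)
    expect_lt(best - got, 1e-6)
  }
})

test_that("a simple-structure solution is a varimax fixed point", {
  L0 <- rbind(matrix(c(0.9, 0), 3, 2, byrow = TRUE),
              matrix(c(0, 0.8), 3, 2, byrow = TRUE))
  sol <- structure(list(R = diag(6), eigenvalues = rep(1, 6),
                        n_retained = 2L, loadings = L0, rotated = FALSE,
                        var_explained = c(0.5, 0.5),
                        total_var_explained = 1, kmo = 0.5),
                   class = "pca_solution")
  rot <- rotate_varimax(sol)
  expect_equal(abs(rot$loadings), L0, tolerance = 1e-6,
               ignore_attr = TRUE)
  # single factor: rotation is the identity
  sol1 <- extract_components(cbind(a = rnorm(30)) %x% t(c(1, 1)) +
                               matrix(rnorm(60, 0, .2), 30))
  rot1 <- rotate_varimax(sol1)
  expect_identical(rot1$rotmat, matrix(1, 1, 1))
})

test_that("regression factor scores are centred and recover simple structure", {
  g <- generate_cohort(cohort_config(), seed = 33)
  fitlist <- impute_cohort(g$cohort, k_grid = 1:2, repetitions = 1, seed = 2)
  co <- orient_measures(fitlist$cohort)
  sm <- collapse_test_measures(co, rows = "patients")
  Zp <- zscore_to_reference(sm, "all")
  sol <- rotate_varimax(extract_components(Zp))
  fs <- factor_scores(sol, Zp)
  expect_lt(max(abs(colMeans(fs$scores))), 1e-8)
  # a row at the patient mean scores zero on every factor
  fs0 <- factor_scores(sol, matrix(0, 1, ncol(Zp$values)))
  expect_lt(max(abs(fs0$scores)), 1e-12)
  # orthogonal unit-loading structure: scores equal the standardised values
  n <- 200; set.seed(4)
  Z2 <- scale(matrix(rnorm(n * 2), n))
  Z2 <- Z2 %*% solve(chol(cov(Z2)))   # exactly uncorrelated, unit sd
  sol2 <- structure(list(R = diag(2), eigenvalues = c(1, 1),
                         n_retained = 2L,
                         loadings = diag(2), rotmat = diag(2),
                         rotated = TRUE, var_explained = c(.5, .5),
                         total_var_explained = 1, kmo = 0.5),
                    class = "pca_solution")
  fs2 <- factor_scores(sol2, Z2)
  expect_equal(unname(fs2$scores), unname(Z2), tolerance = 1e-10)
})

test_that("control projection records norms and the 2-SD cutoff", {
  g <- generate_cohort(cohort_config(), seed = 35)
  fitlist <- impute_cohort(g$cohort, k_grid = 1:2, repetitions = 1, seed = 2)
  co <- orient_measures(fitlist$cohort)
  sm <- collapse_test_measures(co, rows = "patients")
  Zp <- zscore_to_reference(sm, "all")
  sol <- rotate_varimax(extract_components(Zp))
  fs <- factor_scores(sol, Zp)
  ctrl <- apply_collapse(co, sm$plan, rows = "controls")
  Zc <- caseseries:::zscore_apply(ctrl, Zp$reference)
  pr <- project_controls(fs, sol, Zc)
  expect_equal(pr$cutoff, pr$control_mean - 2 * pr$control_sd)
  expect_equal(unname(pr$control_mean),
               unname(colMeans(pr$control_scores)))
  # controls identical to the patient mean profile project to zero
  pr0 <- project_controls(fs, sol, matrix(0, 5, ncol(Zp$values)))
  expect_lt(max(abs(pr0$control_mean)), 1e-12)
  # doubling control SD doubles the mean-to-cutoff distance (linearity)
  Zc2 <- Zc; Zc2$values <- sweep(Zc2$values, 2, colMeans(Zc2$values))
  Zc2$values <- 2 * Zc2$values
  pr2 <- project_controls(fs, sol, Zc2)
  expect_equal(unname(pr2$control_mean - pr2$cutoff),
               unname(2 * (pr$control_mean - pr$cutoff)), tolerance = 1e-8)
  # pseudo-subject cutoff mode agrees on the mean, differs on the spread
  prp <- project_controls(fs, sol, Zc, cutoff_mode = "projected_pseudosubject")
  expect_equal(prp$control_mean, pr$control_mean)
})

test_that("the pipeline is invariant to test column order", {
  g <- generate_cohort(cohort_config(), seed = 37)
  fitlist <- impute_cohort(g$cohort, k_grid = 1:2, repetitions = 1, seed = 2)
  co <- orient_measures(fitlist$cohort)
  sm <- collapse_test_measures(co, rows = "patients")
  Zp <- zscore_to_reference(sm, "all")
  sol <- rotate_varimax(extract_components(Zp))
  perm <- sample(ncol(Zp$values))
  Zp2 <- Zp; Zp2$values <- Zp2$values[, perm]
  sol2 <- rotate_varimax(extract_components(Zp2))
  expect_equal(sol2$eigenvalues, sol$eigenvalues, tolerance = 1e-8)
  expect_equal(sol2$loadings[order(perm), ], sol$loadings,
               tolerance = 1e-6, ignore_attr = TRUE)
})
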