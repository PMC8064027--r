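test_that("noiseless rank-1 data are reconstructed essentially exactly", {
  x <- lowrank_matrix(30, 6, 1, noise_sd = 0, seed = 2)
  f <- fit_ppca(x, 1, seed = 4)
  recon <- sweep(tcrossprod(
    sweep(x, 2, f$mu) %*% f$W %*%
      solve(crossprod(f$W) + f$sigma2 * diag(1)), f$W), 2, f$mu, "+")
  expect_lt(max(abs(recon - x)), 1e-6)
  expect_lt(f$sigma2, 1e-6)
})

test_that("with k = d - 1 the fitted subspace spans the top principal directions", {
  x <- lowrank_matrix(60, 5, 5, noise_sd = 0.3, seed = 6)
  k <- 4
  f <- fit_ppca(x, k, seed = 9, tol = 1e-10, max_iter = 5000)
  ev <- eigen(cov(x), symmetric = TRUE)$vectors[, 1:k]  # oracle subspace
  # largest principal angle between the two k-dim subspaces
  qa <- qr.Q(qr(f$W)); qb <- qr.Q(qr(ev))
  ang <- acos(pmin(1, svd(crossprod(qa, qb))$d))
  expect_lt(max(ang), 1e-4)
})

test_that("EM log-likelihood is monotone non-decreasing with missing data", {
  x <- lowrank_matrix(100, 10, 2, noise_sd = 0.5, missing = 0.1, seed = 8)
  f <- fit_ppca(x, 2, seed = 3)
  expect_true(all(diff(f$loglik_trace) >=
                    -1e-8 * pmax(abs(f$loglik_trace[-1]), 1)))
  expect_true(f$converged)
})

test_that("imputation leaves observed cells bitwise unchanged and completes", {
  x <- lowrank_matrix(40, 8, 2, noise_sd = 0.3, missing = 0.08, seed = 12)
  f <- fit_ppca(x, 2, seed = 5)
  comp <- ppca_impute(x, f)
  obs <- !is.na(x)
  expect_identical(comp[obs], x[obs])
  expect_false(anyNA(comp))
  # no missing entries: identity
  x2 <- lowrank_matrix(20, 5, 2, noise_sd = 0.2, seed = 3)
  f2 <- fit_ppca(x2, 2, seed = 5)
  expect_identical(ppca_impute(x2, f2), x2)
})

test_that("a masked cell of a noiseless rank-1 matrix is forced back", {
  x <- lowrank_matrix(25, 5, 1, noise_sd = 0, seed = 13)
  full <- x
  x[3, 4] <- NA
  f <- fit_ppca(x, 1, seed = 2, tol = 1e-12, max_iter = 5000)
  comp <- ppca_impute(x, f)
  expect_lt(abs(comp[3, 4] - full[3, 4]), 1e-4)
})

test_that("PPCA imputation beats column-mean imputation at 3% MCAR", {
  set.seed(21)
  x <- lowrank_matrix(63, 22, 2, noise_sd = 0.4, seed = 21)
  full <- x
  mask <- matrix(runif(length(x)) < 0.03, nrow(x))
  mask[rowSums(!mask) == 0, 1] <- FALSE
  x[mask] <- NA
  f <- fit_ppca(x, 2, seed = 7)
  comp <- ppca_impute(x, f)
  rmse <- sqrt(mean((comp[mask] - full[mask])^2))
  cm <- matrix(colMeans(x, na.rm = TRUE), nrow(x), ncol(x), byrow = TRUE)
  rmse_cm <- sqrt(mean((cm[mask] - full[mask])^2))
  expect_lt(rmse, rmse_cm)
})

test_that("fit_ppca rejects impossible inputs", {
  x <- lowrank_matrix(10, 4, 1, noise_sd = 0.1)
  expect_error(fit_ppca(x, 4), "smaller than the number of variables")
  expect_error(fit_ppca(x, 0), "k must be")
  x[2, ] <- NA
  expect_error(fit_ppca(x, 1), "row with no observed")
})

test_that("cross-validation report is deterministic and well-formed", {
  x <- lowrank_matrix(30, 6, 2, noise_sd = 0.3, missing = 0.05, seed = 31)
  cv1 <- select_components_cv(x, k_grid = 1:3, repetitions = 1, seed = 17)
  cv2 <- select_components_cv(x, k_grid = 1:3, repetitions = 1, seed = 17)
  expect_identical(cv1$table, cv2$table)
  expect_identical(cv1$chosen_k, cv2$chosen_k)
  expect_true(cv1$chosen_k %in% 1:3)
  expect_true(all(cv1$table$rmse_mean >= 0))
})

test_that("cross-validation recovers the rank of strong-signal data", {
  hits <- 0L
  for (s in 1:10) {
    x <- lowrank_matrix(40, 8, 2, noise_sd = 0.4, missing = 0.1,
                        seed = 100 + s)
    cv <- select_components_cv(x, k_grid = 1:4, folds = 5,
                               repetitions = 1, seed = 200 + s)
    hits <- hits + (cv$chosen_k == 2L)
  }
  expect_gte(hits, 9L)
})

test_that("pure noise selects the single-component model", {
  set.seed(41)
  x <- matrix(rnorm(40 * 8), 40)
  cv <- select_components_cv(x, k_grid = 1:4, folds = 5, repetitions = 3,
                             seed = 19)
  expect_identical(cv$chosen_k, 1L)
})

test_that("row-holdout mode runs and ranks a clear structure sensibly", {
  x <- lowrank_matrix(40, 8, 2, noise_sd = 0.3, seed = 51)
  cv <- select_components_cv(x, k_grid = c(1L, 2L), folds = 4,
                             repetitions = 2, mode = "rows", seed = 23)
  expect_lt(cv$table$rmse_mean[2], cv$table$rmse_mean[1])
})

test_that("cohort-level imputation imputes patients and controls separately", {
  g <- generate_cohort(cohort_config(missing_rate = 0.04), seed = 61)
  imp <- impute_cohort(g$cohort, k_grid = 1:2, repetitions = 1, seed = 3)
  expect_false(anyNA(imp$cohort$values))
  obs <- g$cohort$observed
  expect_identical(imp$cohort$values[obs], g$cohort$values[obs])
  expect_named(imp$models, c("patients", "controls"))
})
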