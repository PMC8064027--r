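# run code with a temporary RNG state seeded at `seed` (NULL = leave RNG alone)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# group rows of an observedness mask by identical pattern
missing_patterns <- function(obs) {
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(obs)), key)
  lapply(idx, function(rows) list(rows = rows, o = which(obs[rows[1L], ])))
}


#' Fit probabilistic PCA by EM on a matrix with missing entries
#'
#' Fits the latent Gaussian model `x = W z + mu + eps`, `z ~ N(0, I_k)`,
#' `eps ~ N(0, sigma2 I)`, by expectation-maximisation over the observed
#' entries only. Both the latent scores and the missing cells are treated as
#' latent variables, so the observed-data log-likelihood is non-decreasing
#' across iterations. The loading matrix is initialised from a random
#' orthonormal basis, making the fit deterministic given `seed`.
#'
#' @param x Numeric matrix (rows = cases); missing cells `NA` or flagged by
#'   `observed`.
#' @param k Number of components, `1 <= k < ncol(x)`.
#' @param observed Logical mask, `FALSE` = missing. Default `!is.na(x)`.
#' @param tol Convergence threshold on the relative change of the
#'   observed-data log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed for the random initialisation.
#' @return An object of class `ppca`: loadings `W` (variables x k), means
#'   `mu`, isotropic noise variance `sigma2` (floored at 1e-12), the
#'   per-iteration `loglik_trace`, and convergence information.
#' @export
fit_ppca <- function(x, k, observed = !is.na(x), tol = 1e-6,
                     max_iter = 1000L, seed = NULL) {
  stopifnot(is.matrix(x), is.logical(observed),
            identical(dim(observed), dim(x)))
  n <- nrow(x); d <- ncol(x)
  if (k < 1L) stop("k must be >= 1")
  if (k >= d) stop("k must be smaller than the number of variables (", d, ")")
  if (any(rowSums(observed) == 0L)) stop("row with no observed entries")
  if (any(colSums(observed) == 0L)) stop("column with no observed entries")
  x[!observed] <- NA_real_

  mu <- colMeans(x, na.rm = TRUE)
  colvar <- apply(x, 2, stats::var, na.rm = TRUE)
  colvar[is.na(colvar) | colvar == 0] <- 1
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(d * k), d, k))) * sqrt(mean(colvar))
  })
  s2 <- mean(colvar) / 2
  x0 <- x
  x0[!observed] <- 0                     # placeholder; masked cells unused
  fit <- .ppca_em_cpp(x0, matrix(as.integer(observed), n, d), W, mu, s2,
                      tol, as.integer(max_iter))
  W <- fit$W
  rownames(W) <- colnames(x)
  mu <- drop(fit$mu)
  names(mu) <- colnames(x)
  structure(list(k = k, W = W, mu = mu, sigma2 = fit$sigma2,
                 loglik_trace = drop(fit$loglik_trace),
                 n_iter = fit$n_iter, converged = fit$converged,
                 tol = tol, seed = seed, dim = c(n = n, d = d)),
            class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  cat(sprintf("<ppca> k = %d on %d x %d matrix; sigma2 = %.4g; %s after %d iterations\n",
              x$k, x$dim["n"], x$dim["d"], x$sigma2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Impute missing entries with a fitted PPCA model
#'
#' Observed entries are returned unchanged (bitwise); missing entries are
#' replaced by their posterior-mean reconstruction given the row's observed
#' entries under the fitted model.
#'
#' @param x Numeric matrix with `NA` for missing entries (or use `observed`).
#' @param model A fitted [fit_ppca()] object on the same variable set.
#' @param observed Logical mask, `FALSE` = missing.
#' @return The completed matrix.
#' @export
ppca_impute <- function(x, model, observed = !is.na(x)) {
  stopifnot(inherits(model, "ppca"))
  if (ncol(x) != length(model$mu))
    stop("matrix has ", ncol(x), " columns but the model was fitted on ",
         length(model$mu))
  if (!any(!observed)) return(x)
  if (any(rowSums(observed) == 0L)) stop("row with no observed entries")
  out <- x
  Ik <- diag(model$k)
  for (p in missing_patterns(observed)) {
    m <- setdiff(seq_len(ncol(x)), p$o)
    if (!length(m)) next
    Wo <- model$W[p$o, , drop = FALSE]
    Wm <- model$W[m, , drop = FALSE]
    Minv <- solve(crossprod(Wo) + model$sigma2 * Ik)
    Xc <- sweep(x[p$rows, p$o, drop = FALSE], 2, model$mu[p$o])
    Ez <- Xc %*% Wo %*% Minv
    out[p$rows, m] <- sweep(Ez %*% t(Wm), 2, model$mu[m], "+")
  }
  out
}

#' @export
predict.ppca <- function(object, newdata, ...) {
  ppca_impute(newdata, object)
}

#' Choose the PPCA component count by cross-validated imputation error
#'
#' Element-wise holdout: per repetition the observed cells are partitioned
#' into `folds` sets (each fold leaving every row and column of the training
#' mask observed at least once); each fold is masked in turn, the model
#' refitted on the rest, and the root mean squared reconstruction error
#' evaluated on the held-out cells. The chosen component count is the global
#' argmin of the mean RMSE, with ties broken toward the smaller count.
#'
#' @param x Numeric matrix (`NA` = missing).
#' @param k_grid Candidate component counts.
#' @param folds Number of folds (default 5).
#' @param repetitions Number of independent fold-assignment redraws.
#' @param holdout Optional fraction of observed cells; if given, each
#'   repetition draws a single random holdout of this size instead of a
#'   k-fold partition.
#' @param mode `"cells"` (element-wise holdout, default) or `"rows"`
#'   (whole-row holdout; held-out rows are reconstructed from their own
#'   observed cells through the trained model).
#' @param observed Logical mask, `FALSE` = missing.
#' @param seed Integer seed; fold assignments and fits derive from it.
#' @param tol,max_iter Passed to the internal [fit_ppca()] calls.
#' @return An object of class `ppca_cv`: a table of mean/SD RMSE per
#'   candidate `k`, the chosen count, and the resampling settings.
#' @export
select_components_cv <- function(x, k_grid = 1:5, folds = 5L,
                                 repetitions = 100L, holdout = NULL,
                                 mode = c("cells", "rows"),
                                 observed = !is.na(x), seed = NULL,
                                 tol = 1e-5, max_iter = 500L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), all(k_grid >= 1L), all(k_grid < ncol(x)))
  k_grid <- sort(unique(as.integer(k_grid)))
  x[!observed] <- NA_real_
  rmse <- array(NA_real_, c(length(k_grid), repetitions,
                            if (is.null(holdout)) folds else 1L))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (r in seq_len(repetitions)) {
    sets <- with_seed(if (is.null(base_seed)) NULL else base_seed + r,
                      cv_holdout_sets(observed, folds, holdout, mode))
    for (ki in seq_along(k_grid)) {
      for (fi in seq_along(sets)) {
        hold <- sets[[fi]]
        fit_seed <- if (is.null(base_seed)) NULL else
          base_seed + 7919L * ki + r
        if (mode == "rows") {
          fit <- fit_ppca(x[-hold, , drop = FALSE], k_grid[ki],
                          observed = observed[-hold, , drop = FALSE],
                          tol = tol, max_iter = max_iter, seed = fit_seed)
          err2 <- 0; nc <- 0L
          for (i in hold) {
            o <- which(observed[i, ])
            Wo <- fit$W[o, , drop = FALSE]
            Ez <- drop(solve(crossprod(Wo) + fit$sigma2 * diag(fit$k),
                             crossprod(Wo, x[i, o] - fit$mu[o])))
            xh <- fit$mu[o] + drop(Wo %*% Ez)
            err2 <- err2 + sum((xh - x[i, o])^2); nc <- nc + length(o)
          }
          rmse[ki, r, fi] <- sqrt(err2 / nc)
        } else {
          train_obs <- observed
          train_obs[hold] <- FALSE
          fit <- fit_ppca(x, k_grid[ki], observed = train_obs, tol = tol,
                          max_iter = max_iter, seed = fit_seed)
          comp <- ppca_impute(x, fit, observed = train_obs)
          rmse[ki, r, fi] <- sqrt(mean((comp[hold] - x[hold])^2))
        }
      }
    }
  }
  tab <- data.frame(k = k_grid,
                    rmse_mean = apply(rmse, 1, mean),
                    rmse_sd = apply(rmse, 1, stats::sd))
  chosen <- k_grid[which.min(tab$rmse_mean)]
  structure(list(table = tab, chosen_k = chosen, folds = folds,
                 repetitions = repetitions, holdout = holdout, mode = mode,
                 seed = seed),
            class = "ppca_cv")
}

# draw holdout cell sets (linear indices) for one repetition
cv_holdout_sets <- function(observed, folds, holdout, mode) {
  if (mode == "rows") {
    rows <- sample(nrow(observed))
    return(unname(split(rows, cut(seq_along(rows), folds, labels = FALSE))))
  }
  cells <- which(observed)
  if (!is.null(holdout)) {
    stopifnot(holdout > 0, holdout < 1)
    sets <- list(sample(cells, max(1L, round(holdout * length(cells)))))
  } else {
    perm <- sample(cells)
    sets <- split(perm, cut(seq_along(perm), folds, labels = FALSE))
  }
  for (attempt in 1:50) {
    ok <- all(vapply(sets, function(hold) {
      tr <- observed; tr[hold] <- FALSE
      all(rowSums(tr) > 0L) && all(colSums(tr) > 0L)
    }, TRUE))
    if (ok) return(sets)
    if (!is.null(holdout)) {
      sets <- list(sample(cells, length(sets[[1L]])))
    } else {
      perm <- sample(cells)
      sets <- split(perm, cut(seq_along(perm), folds, labels = FALSE))
    }
  }
  stop("could not build a feasible holdout partition; try fewer folds")
}

#' @export
print.ppca_cv <- function(x, ...) {
  cat(sprintf("<ppca_cv> chosen k = %d (%d-fold x %d repetitions, %s holdout)\n",
              x$chosen_k, x$folds, x$repetitions, x$mode))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Impute a cohort's missing scores by PPCA
#'
#' Patients and controls are imputed by separately fitted models so that
#' patient pathology never shapes control imputations. Score columns are
#' z-scored (observed mean/SD per column) before fitting so that the
#' isotropic-noise assumption is reasonable across measures on different
#' scales, and imputed values are mapped back. The component count for each
#' subcohort is selected by [select_components_cv()] on that subcohort
#' (skipped when it has no missing cells).
#'
#' @param cohort A [cohort_table].
#' @param k_grid,folds,repetitions Passed to [select_components_cv()].
#' @param seed Integer seed.
#' @return A list: `cohort` (completed [cohort_table]), `cv` (per-subcohort
#'   [select_components_cv()] reports), `models` (fitted [fit_ppca()]
#'   objects).
#' @export
impute_cohort <- function(cohort, k_grid = 1:5, folds = 5L,
                          repetitions = 5L, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  grp <- cohort$participants$group
  out <- cohort
  cv <- list(); models <- list()
  for (sub in c("patients", "controls")) {
    idx <- if (sub == "patients") which(grp != "control") else
      which(grp == "control")
    if (!length(idx)) next
    obs <- cohort$observed[idx, , drop = FALSE]
    if (all(obs)) next
    xs <- cohort$values[idx, , drop = FALSE]
    cmu <- colMeans(xs, na.rm = TRUE)
    csd <- apply(xs, 2, stats::sd, na.rm = TRUE)
    if (any(is.na(csd) | csd == 0))
      stop("cannot impute: a column is constant or near-empty in the ",
           sub, " subcohort")
    zs <- sweep(sweep(xs, 2, cmu), 2, csd, "/")
    sub_seed <- if (is.null(seed)) NULL else
      seed + if (sub == "patients") 1L else 2L
    kg <- k_grid[k_grid < min(dim(zs))]
    cvr <- select_components_cv(zs, k_grid = kg, folds = folds,
                                repetitions = repetitions, observed = obs,
                                seed = sub_seed)
    fit <- fit_ppca(zs, cvr$chosen_k, observed = obs, seed = sub_seed)
    compz <- ppca_impute(zs, fit, observed = obs)
    comp <- sweep(sweep(compz, 2, csd, "*"), 2, cmu, "+")
    comp[obs] <- xs[obs]                 # observed cells bitwise unchanged
    out$values[idx, ] <- comp
    out$observed[idx, ] <- TRUE
    cv[[sub]] <- cvr; models[[sub]] <- fit
  }
  list(cohort = out, cv = cv, models = models)
}
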