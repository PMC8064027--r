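#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares the magnitude of the observed correlations to the magnitude of
#' the anti-image partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over `i != j`, where
#' `q_ij = -r^{ij} / sqrt(r^{ii} r^{jj})` is formed from the inverse of the
#' correlation matrix.
#'
#' @param R Correlation matrix: symmetric, positive definite, unit diagonal.
#' @return KMO in (0, 1].
#' @export
kmo <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have a unit diagonal")
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; regularize or drop collinear ",
         "tests before computing KMO", call. = FALSE))
  s <- sqrt(diag(Rinv))
  Q <- -Rinv / tcrossprod(s)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  if (r2 + q2 == 0)
    stop("KMO undefined: all off-diagonal correlations are zero")
  r2 / (r2 + q2)
}

#' Extract principal components from a standardised score matrix
#'
#' Eigen-decomposes the test correlation matrix and retains every component
#' with eigenvalue strictly greater than 1 (Kaiser rule); if none qualifies a
#' single component is retained. Loadings are eigenvectors scaled by the
#' square root of their eigenvalue, sign-fixed so the largest-magnitude
#' loading in each column is positive.
#'
#' @param Z A [score_matrix] (typically patient rows z-scored to the patient
#'   group) or a plain numeric matrix.
#' @return An object of class `pca_solution` holding the correlation matrix,
#'   eigenvalues, retained unrotated loadings, variance explained and the
#'   KMO measure. Rotation-related fields are filled by [rotate_varimax()].
#' @export
extract_components <- function(Z) {
  M <- if (inherits(Z, "score_matrix")) Z$values else Z
  stopifnot(is.matrix(M), ncol(M) >= 2L)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  R <- stats::cor(M)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  nr <- sum(lambda > 1)
  if (nr == 0L) nr <- 1L
  L <- e$vectors[, seq_len(nr), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(nr)]), nr)
  L <- fix_signs(L)
  rownames(L) <- colnames(M)
  colnames(L) <- paste0("F", seq_len(nr))
  structure(list(R = R, eigenvalues = lambda, n_retained = nr,
                 loadings = L, rotmat = NULL, rotated = FALSE,
                 var_explained = lambda[seq_len(nr)] / ncol(M),
                 total_var_explained = sum(lambda[seq_len(nr)]) / ncol(M),
                 # undefined for singular/orthogonal R; extraction still valid
                 kmo = tryCatch(kmo(R), error = function(e) NA_real_)),
            class = "pca_solution")
}

# flip column signs so the largest-|loading| entry of each column is positive
fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Varimax-rotate a PCA solution
#'
#' Applies an orthogonal varimax rotation (maximising the summed variance of
#' squared, optionally Kaiser row-normalised, loadings) to the retained
#' loadings. Columns are sign-fixed (largest-magnitude loading positive) and
#' reordered by post-rotation variance explained, descending; the rotation
#' matrix is updated accordingly, so communalities and the total variance
#' explained are unchanged. A single-factor solution is returned as-is with
#' an identity rotation.
#'
#' @param solution A [extract_components()] result.
#' @param kaiser_normalize Normalise rows to unit communality during the
#'   rotation (default `TRUE`).
#' @param tol Convergence tolerance on the relative change of the rotation
#'   criterion.
#' @return The solution with rotated `loadings`, orthogonal `rotmat`,
#'   per-factor `var_explained`, and `rotated = TRUE`.
#' @export
rotate_varimax <- function(solution, kaiser_normalize = TRUE, tol = 1e-6) {
  stopifnot(inherits(solution, "pca_solution"))
  L0 <- solution$loadings
  nf <- ncol(L0)
  if (nf == 1L) {
    solution$rotmat <- matrix(1, 1, 1)
    solution$rotated <- TRUE
    return(solution)
  }
  v <- stats::varimax(L0, normalize = kaiser_normalize, eps = tol)
  L <- L0 %*% v$rotmat
  Tm <- v$rotmat
  # sign fix
  for (j in seq_len(nf)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; Tm[, j] <- -Tm[, j] }
  }
  # order by variance explained (sum of squared loadings), descending
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  colnames(L) <- paste0("F", seq_len(nf))
  if (max(abs(crossprod(Tm) - diag(nf))) > 1e-8)
    stop("rotation matrix is not orthogonal")
  solution$loadings <- L
  solution$rotmat <- Tm
  solution$var_explained <- colSums(L^2) / nrow(L)
  solution$rotated <- TRUE
  solution
}

# varimax criterion: summed variance of squared (row-normalised) loadings
varimax_criterion <- function(L, kaiser_normalize = TRUE) {
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  L2 <- L^2
  sum(apply(L2, 2, function(col) mean((col - mean(col))^2)))
}

#' @export
print.pca_solution <- function(x, ...) {
  cat(sprintf("<pca_solution> %d tests, %d factor(s)%s; KMO = %.3f; %.0f%% variance explained\n",
              nrow(x$loadings), x$n_retained,
              if (x$rotated) " (varimax-rotated)" else " (unrotated)",
              x$kmo, 100 * x$total_var_explained))
  invisible(x)
}

#' Compute factor scores by the regression method
#'
#' Factor-score coefficients are `Ws = R^-1 Lambda`; scores are `Z Ws`. On
#' the fitting (patient) sample regression scores have mean zero on every
#' factor.
#'
#' @param solution A (rotated) [extract_components()] solution.
#' @param Z A [score_matrix] or plain matrix standardised with the patient
#'   reference.
#' @return An object of class `factor_scores` with the score matrix and the
#'   coefficient matrix `Ws`; control statistics are added by
#'   [project_controls()].
#' @export
factor_scores <- function(solution, Z) {
  stopifnot(inherits(solution, "pca_solution"))
  M <- if (inherits(Z, "score_matrix")) Z$values else Z
  if (ncol(M) != nrow(solution$loadings))
    stop("score matrix has ", ncol(M), " columns but the solution has ",
         nrow(solution$loadings), " tests")
  Ws <- solve(solution$R, solution$loadings)
  scores <- M %*% Ws
  colnames(scores) <- colnames(solution$loadings)
  structure(list(scores = scores, Ws = Ws,
                 control_scores = NULL, control_mean = NULL,
                 control_sd = NULL, cutoff = NULL, cutoff_mode = NULL),
            class = "factor_scores")
}

#' Project control norms and impairment cutoffs into the patient PCA space
#'
#' Controls, z-scored with the patient means and SDs, are mapped through the
#' patient solution's factor-score coefficients. The control mean and SD per
#' factor and the impairment cutoff (control mean minus two control SDs) are
#' recorded. `cutoff_mode = "score_sd"` (default) takes the SD of the
#' per-control factor scores; `"projected_pseudosubject"` instead projects a
#' pseudo-subject lying two control SDs below the control mean on every
#' test.
#'
#' @param fs A [factor_scores] object from the patient solution.
#' @param solution The corresponding [extract_components()] solution.
#' @param Zc Control score matrix already standardised with the *patient*
#'   reference statistics (no missing entries; impute first).
#' @param cutoff_mode `"score_sd"` or `"projected_pseudosubject"`.
#' @return `fs` augmented with `control_scores`, `control_mean`,
#'   `control_sd` and per-factor `cutoff`.
#' @export
project_controls <- function(fs, solution, Zc,
                             cutoff_mode = c("score_sd",
                                             "projected_pseudosubject")) {
  cutoff_mode <- match.arg(cutoff_mode)
  M <- if (inherits(Zc, "score_matrix")) Zc$values else Zc
  if (anyNA(M)) stop("control matrix has missing entries; impute first")
  if (ncol(M) != nrow(solution$loadings))
    stop("control matrix columns do not match the patient solution")
  cs <- M %*% fs$Ws
  colnames(cs) <- colnames(solution$loadings)
  cm <- colMeans(cs)
  csd <- apply(cs, 2, stats::sd)
  cut <- if (cutoff_mode == "score_sd") {
    cm - 2 * csd
  } else {
    mz <- colMeans(M)
    sz <- apply(M, 2, stats::sd)
    drop((mz - 2 * sz) %*% fs$Ws)
  }
  fs$control_scores <- cs
  fs$control_mean <- cm
  fs$control_sd <- csd
  fs$cutoff <- cut
  fs$cutoff_mode <- cutoff_mode
  fs
}

#' Tucker congruence between two loading matrices
#'
#' Cosine similarity per factor after greedily matching columns of `B` to
#' columns of `A` by absolute congruence (signs are immaterial).
#'
#' @param A,B Loading matrices with the same number of rows.
#' @return Numeric vector of per-matched-factor congruence coefficients (in
#'   `A`'s column order).
#' @export
tucker_congruence <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  cg <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  avail <- seq_len(ncol(B))
  out <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    vals <- vapply(avail, function(bj) cg(A[, j], B[, bj]), 0)
    pick <- which.max(vals)
    out[j] <- vals[pick]
    avail <- avail[-pick]
    if (!length(avail)) { out <- out[seq_len(j)]; break }
  }
  out
}
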