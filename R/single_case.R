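# tail-adjust a vector of lower-tail probabilities
tail_adjust <- function(p_low, tail) {
  switch(tail,
         lower = p_low,
         upper = 1 - p_low,
         two = pmin(1, 2 * pmin(p_low, 1 - p_low)))
}

# 95% interval from Monte-Carlo draws, widened to contain the point estimate
mc_interval <- function(draws, point) {
  q <- unname(stats::quantile(draws, c(0.025, 0.975)))
  c(min(q[1], point), max(q[2], point))
}

#' Crawford-Howell modified t-test for a single case
#'
#' Compares one case to a small control sample treating the control
#' statistics as sample estimates:
#' `t = (y_star - mean(y)) / (sd(y) * sqrt((n + 1) / n))` on `n - 1` degrees
#' of freedom. The lower-tail p is also the point estimate of the percentage
#' of the control population expected to score below the case.
#'
#' @param y Control scores (length >= 3, non-constant).
#' @param y_star Case score.
#' @param tail `"lower"` (deficit, default), `"upper"`, or `"two"`.
#' @return An object of class `single_case` with the t statistic, degrees of
#'   freedom, p-value for the requested tail, abnormality percentage, and
#'   the case-controls effect size `z_cc`.
#' @export
crawford_howell_t <- function(y, y_star, tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  n <- length(y)
  if (n < 3L) stop("at least 3 controls are required")
  s <- stats::sd(y)
  if (s == 0) stop("control scores are constant")
  tstat <- (y_star - mean(y)) / (s * sqrt((n + 1) / n))
  p_low <- stats::pt(tstat, df = n - 1)
  structure(list(statistic = tstat, df = n - 1,
                 p = unname(tail_adjust(p_low, tail)), tail = tail,
                 abnormality_pct = 100 * p_low,
                 abnormality_ci = NULL,
                 z_cc = (y_star - mean(y)) / s,
                 method = "crawford_howell_t", n = n),
            class = "single_case")
}

#' Bayesian test for a deficit allowing for covariates
#'
#' Compares a case's score to controls conditioning on covariates, by
#' Monte-Carlo sampling from the posterior of the control regression under
#' non-informative priors. Per draw, the residual variance is sampled as
#' `SSE / chi2(nu)` with `nu = n - c - 1`, the coefficient vector from a
#' multivariate normal around the least-squares estimate, and the case's
#' conditional z and lower-tail probability are recorded. The reported p is
#' the posterior mean (tail-adjusted); with no covariates it converges to
#' the Crawford-Howell analytic p.
#'
#' @param y Control scores (length n).
#' @param y_star Case score.
#' @param X Control covariate matrix (n x c) or vector, or `NULL` for no
#'   covariates.
#' @param x_star Case covariate values (length c).
#' @param tail `"lower"` (default), `"upper"`, or `"two"`.
#' @param n_mc Monte-Carlo draws (>= 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @return An object of class `single_case`: posterior `p` with 95% credible
#'   interval, abnormality percentage (100 x lower-tail p) with interval,
#'   and the conditional effect size `z_ccc` evaluated at the point
#'   estimates.
#' @export
btd_cov <- function(y, y_star, X = NULL, x_star = NULL,
                    tail = c("lower", "upper", "two"),
                    n_mc = 10000L, seed = NULL) {
  tail <- match.arg(tail)
  if (n_mc < 1000L) stop("n_mc must be at least 1000")
  n <- length(y)
  if (!is.null(X)) X <- as.matrix(X)
  cc <- if (is.null(X)) 0L else ncol(X)
  if (n <= cc + 2L)
    stop("need n > c + 2 controls (n = ", n, ", c = ", cc, ")")
  if (cc > 0L) {
    if (nrow(X) != n) stop("X must have one row per control")
    if (length(x_star) != cc) stop("x_star must have length ", cc)
    if (any(apply(X, 2, stats::sd) == 0))
      stop("covariate with zero variance")
  }
  D <- cbind(rep(1, n), X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("collinear covariate design")
  b <- qr.coef(qrD, y)
  res <- y - D %*% b
  SSE <- sum(res^2)
  if (SSE <= 0) stop("control scores are perfectly predicted; sd is zero")
  nu <- n - cc - 1L
  A <- chol2inv(qr.R(qrD))
  U <- chol(A)
  x1 <- c(1, x_star)

  p_low <- with_seed(seed, {
    sig2 <- SSE / stats::rchisq(n_mc, df = nu)
    Zm <- matrix(stats::rnorm((cc + 1L) * n_mc), cc + 1L, n_mc)
    cond <- drop(crossprod(x1, b)) +
      drop(crossprod(x1, t(U) %*% Zm)) * sqrt(sig2)
    stats::pnorm((y_star - cond) / sqrt(sig2))
  })
  p_draws <- tail_adjust(p_low, tail)
  p <- mean(p_draws)
  z_ccc <- (y_star - drop(crossprod(x1, b))) / sqrt(SSE / nu)
  structure(list(p = p, ci = mc_interval(p_draws, p), tail = tail,
                 abnormality_pct = 100 * mean(p_low),
                 abnormality_ci = 100 * mc_interval(p_low, mean(p_low)),
                 z_ccc = z_ccc, n = n, c = cc, n_mc = n_mc, seed = seed,
                 method = "btd_cov"),
            class = "single_case")
}

#' @export
print.single_case <- function(x, ...) {
  cat(sprintf("<single_case: %s> p (%s) = %.4g", x$method, x$tail, x$p))
  if (!is.null(x$ci))
    cat(sprintf(" [%.4g, %.4g]", x$ci[1], x$ci[2]))
  z <- if (!is.null(x$z_ccc)) x$z_ccc else x$z_cc
  cat(sprintf("; abnormality %.2f%%; z = %.3f\n", x$abnormality_pct, z))
  invisible(x)
}

#' Bayesian standardised difference test allowing for covariates
#'
#' Tests whether a case's standardised difference between two tasks is
#' abnormal relative to controls, conditioning on covariates. Per draw the
#' residual covariance of the bivariate control regression is sampled from
#' an inverse-Wishart (scale = residual cross-product `S`, df `n - c - 1`;
#' the `standard_theory` prior), the coefficient matrix from a matrix normal
#' with row covariance `A = (D'D)^-1` and column covariance the drawn Sigma,
#' and the case's standardised difference
#' `d = (z_x - z_y) / sqrt(2 - 2 rho)` is converted to a normal tail
#' probability. The reported p is the posterior mean, tail-adjusted.
#'
#' @param Y Control scores, n x 2 matrix (task X, task Y).
#' @param y_star Case scores on the two tasks (length 2).
#' @param X Control covariate matrix (n x c) or `NULL`.
#' @param x_star Case covariates (length c).
#' @param tail `"two"` (default), `"lower"`, or `"upper"`.
#' @param prior `"standard_theory"` (implemented) or `"calibrated"`
#'   (reserved; not implemented).
#' @param n_mc Monte-Carlo draws (>= 1000).
#' @param seed Integer seed.
#' @return An object of class `diff_case`: `p_diff` with credible interval,
#'   the case's per-task conditional z at the point estimates, and the
#'   estimated conditional correlation `rho`.
#' @export
bsdt_cov <- function(Y, y_star, X = NULL, x_star = NULL,
                     tail = c("two", "lower", "upper"),
                     prior = c("standard_theory", "calibrated"),
                     n_mc = 10000L, seed = NULL) {
  tail <- match.arg(tail)
  prior <- match.arg(prior)
  if (prior == "calibrated")
    stop("the 'calibrated' prior is reserved and not implemented; ",
         "use prior = 'standard_theory'")
  if (n_mc < 1000L) stop("n_mc must be at least 1000")
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2L, length(y_star) == 2L)
  n <- nrow(Y)
  if (!is.null(X)) X <- as.matrix(X)
  cc <- if (is.null(X)) 0L else ncol(X)
  if (n < cc + 4L)
    stop("need n >= c + 4 controls (n = ", n, ", c = ", cc, ")")
  if (any(apply(Y, 2, stats::sd) == 0))
    stop("a task score column is constant")
  D <- cbind(rep(1, n), X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("collinear covariate design")
  B <- qr.coef(qrD, Y)                       # (c+1) x 2
  E <- Y - D %*% B
  S <- crossprod(E)
  nu <- n - cc - 1L
  rho_hat <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (abs(rho_hat) >= 1 - 1e-10)
    stop("conditional task correlation is (near) unity; ",
         "the standardised difference is undefined")
  A <- chol2inv(qr.R(qrD))
  UA <- chol(A)
  x1 <- c(1, x_star)

  p_low <- with_seed(seed, {
    Winv <- stats::rWishart(n_mc, df = nu, Sigma = solve(S))
    a <- Winv[1, 1, ]; bq <- Winv[1, 2, ]; d <- Winv[2, 2, ]
    det <- a * d - bq^2
    S11 <- d / det; S22 <- a / det; S12 <- -bq / det
    # lower Cholesky of each drawn Sigma
    l11 <- sqrt(S11)
    l21 <- S12 / l11
    l22 <- sqrt(pmax(S22 - l21^2, 1e-300))
    G1 <- drop(crossprod(x1, t(UA) %*%
                           matrix(stats::rnorm((cc + 1L) * n_mc),
                                  cc + 1L, n_mc)))
    G2 <- drop(crossprod(x1, t(UA) %*%
                           matrix(stats::rnorm((cc + 1L) * n_mc),
                                  cc + 1L, n_mc)))
    m1 <- drop(crossprod(x1, B[, 1])) + G1 * l11
    m2 <- drop(crossprod(x1, B[, 2])) + G1 * l21 + G2 * l22
    z_x <- (y_star[1] - m1) / sqrt(S11)
    z_y <- (y_star[2] - m2) / sqrt(S22)
    rho <- S12 / sqrt(S11 * S22)
    stats::pnorm((z_x - z_y) / sqrt(2 - 2 * rho))
  })
  p_draws <- tail_adjust(p_low, tail)
  p <- mean(p_draws)
  sig_hat <- sqrt(diag(S) / nu)
  z_pt <- (y_star - drop(crossprod(x1, B))) / sig_hat
  structure(list(p_diff = p, ci = mc_interval(p_draws, p), tail = tail,
                 z_x = z_pt[1], z_y = z_pt[2], rho = rho_hat,
                 n = n, c = cc, n_mc = n_mc, seed = seed, prior = prior),
            class = "diff_case")
}

#' @export
print.diff_case <- function(x, ...) {
  cat(sprintf("<diff_case: bsdt_cov> p_diff (%s) = %.4g [%.4g, %.4g]; z_x = %.2f, z_y = %.2f, rho = %.2f\n",
              x$tail, x$p_diff, x$ci[1], x$ci[2], x$z_x, x$z_y, x$rho))
  invisible(x)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t`, `df` (`n1 + n2 - 2`) and the two-tailed `p`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0) stop("both standard deviations are zero")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}
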