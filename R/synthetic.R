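#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated case-series cohort: a
#' two-factor latent ability model (word/object and face/object), age
#' dependence, lesion-laterality and lesion-volume effects, optional planted
#' category-selective cases, and completely-at-random missingness.
#'
#' Default loadings give word tests (0.8, 0.1), face tests (0.1, 0.8),
#' object tests (0.5, 0.5) and low-level tests (0.3, 0.3) on the two latent
#' factors, reproducing a word/object versus face/object factor split.
#' Default per-test noise SDs (word 0.35, object 0.40, face 0.45, low-level
#' 0.55) make control performance least variable on word tests and most
#' variable on face/low-level tests.
#'
#' @param n_controls,n_left,n_right,n_bilateral Group sizes (defaults 46,
#'   32, 23, 9).
#' @param factor_corr Correlation between the two latent abilities
#'   (default 0.25).
#' @param loading_table Tests x 2 matrix of generating loadings; default
#'   derived from the schema's domains as above.
#' @param age_effect Per-test slope on z-scored age (default -0.15,
#'   recycled).
#' @param noise_sd Per-test residual SD (default by domain as above,
#'   recycled if scalar).
#' @param delta_left,delta_right,delta_bilateral Lesion effects: mean latent
#'   shift (in latent SD units) on factor 1 for left lesions, factor 2 for
#'   right lesions, and both factors for bilateral lesions (defaults 0.6).
#' @param volume_scaling Scale each patient's shift by lesion volume
#'   relative to the cohort median (default `TRUE`).
#' @param within_test_cor Target correlation between the accuracy and RT
#'   measures of two-measure tests (default 0.8).
#' @param planted_cases List of `list(domain =, delta =, count =)` entries:
#'   `count` patients receive an extra deficit of `delta` control SDs on
#'   every test of `domain`.
#' @param missing_rate Fraction of score cells set missing completely at
#'   random (default 0.03).
#' @param schema Battery schema (default [vot_battery()]).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 46L, n_left = 32L, n_right = 23L,
                          n_bilateral = 9L, factor_corr = 0.25,
                          loading_table = NULL, age_effect = -0.15,
                          noise_sd = NULL, delta_left = 0.6,
                          delta_right = 0.6, delta_bilateral = 0.6,
                          volume_scaling = TRUE, within_test_cor = 0.8,
                          planted_cases = list(), missing_rate = 0.03,
                          schema = vot_battery()) {
  stopifnot(n_controls >= 0, n_left >= 0, n_right >= 0, n_bilateral >= 0,
            abs(factor_corr) < 1, missing_rate >= 0, missing_rate < 0.5,
            within_test_cor > 0, within_test_cor < 1)
  nt <- length(schema)
  doms <- vapply(schema, `[[`, "", "domain")
  if (is.null(loading_table)) {
    loading_table <- t(vapply(doms, function(d) switch(
      d, word = c(0.8, 0.1), face = c(0.1, 0.8), object = c(0.5, 0.5),
      c(0.3, 0.3)), numeric(2)))
  }
  stopifnot(nrow(loading_table) == nt, ncol(loading_table) == 2L)
  rownames(loading_table) <- names(schema)
  if (is.null(noise_sd)) {
    noise_sd <- vapply(doms, function(d) switch(
      d, word = 0.35, object = 0.40, face = 0.45, 0.55), 0)
  }
  noise_sd <- rep_len(noise_sd, nt)
  age_effect <- rep_len(age_effect, nt)
  n_pat <- n_left + n_right + n_bilateral
  planted_n <- sum(vapply(planted_cases, function(p) p$count, 0))
  if (planted_n > n_pat)
    stop("more planted cases (", planted_n, ") than patients (", n_pat, ")")
  for (p in planted_cases)
    stopifnot(p$domain %in% c("word", "object", "face"), p$delta >= 0,
              p$count >= 0)
  structure(list(n_controls = n_controls, n_left = n_left,
                 n_right = n_right, n_bilateral = n_bilateral,
                 factor_corr = factor_corr, loading_table = loading_table,
                 age_effect = age_effect, noise_sd = noise_sd,
                 delta_left = delta_left, delta_right = delta_right,
                 delta_bilateral = delta_bilateral,
                 volume_scaling = volume_scaling,
                 within_test_cor = within_test_cor,
                 planted_cases = planted_cases,
                 missing_rate = missing_rate, schema = schema),
            class = "cohort_config")
}

# total variance of each test's latent score under a config (control model)
implied_test_var <- function(config) {
  Phi <- matrix(c(1, config$factor_corr, config$factor_corr, 1), 2)
  L <- config$loading_table
  diag(L %*% Phi %*% t(L)) + config$age_effect^2 + config$noise_sd^2
}

#' Generate a synthetic case-series cohort with ground truth
#'
#' Per participant a latent ability pair is drawn from a bivariate normal;
#' patients receive a negative lesion shift on the lateralised factor(s),
#' scaled by a lognormal lesion volume; each test's latent score is the
#' loading-weighted ability plus an age effect (on z-scored age) and
#' independent noise; planted category-selective cases receive an extra
#' deficit on every test of their domain. Two-measure tests emit accuracy
#' and RT measures correlated at the configured level; scores are mapped to
#' plausible units (accuracy around 80, RT around 800 ms, lower better).
#' A missingness mask is drawn completely at random. Deterministic given
#' `seed`.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort`: `cohort` (a [cohort_table]),
#'   `truth` (per-participant latent factors, applied group shifts, planted
#'   labels and effect sizes, the generating loading table, and the
#'   complete pre-masking score matrix).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, generate_cohort_impl(config, seed))
}

generate_cohort_impl <- function(config, seed) {
  schema <- config$schema
  nt <- length(schema)
  groups <- rep(c("control", "left", "right", "bilateral"),
                c(config$n_controls, config$n_left, config$n_right,
                  config$n_bilateral))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  is_pat <- groups != "control"

  age <- pmin(pmax(stats::rnorm(n, ifelse(is_pat, 60.9, 61.5),
                                ifelse(is_pat, 13.1, 14.6)), 25), 92)
  education <- pmax(stats::rnorm(n, ifelse(is_pat, 14.0, 15.2),
                                 ifelse(is_pat, 2.7, 1.9)), 8)
  lesion_volume <- rep(NA_real_, n)
  tss <- rep(NA_real_, n)
  vol_mean <- c(left = 31.8, right = 34.7, bilateral = 61.4)
  for (g in names(vol_mean)) {
    gi <- which(groups == g)
    lesion_volume[gi] <- stats::rlnorm(
      length(gi), log(vol_mean[[g]]) - 0.8^2 / 2, 0.8)
    tss[gi] <- stats::rlnorm(length(gi), log(40) - 0.9^2 / 2, 0.9)
  }

  Phi <- matrix(c(1, config$factor_corr, config$factor_corr, 1), 2)
  a <- MASS::mvrnorm(n, c(0, 0), Phi)
  shift <- matrix(0, n, 2)
  vscale <- rep(1, n)
  if (config$volume_scaling && any(is_pat))
    vscale[is_pat] <- lesion_volume[is_pat] /
      stats::median(lesion_volume[is_pat])
  shift[groups == "left", 1] <- config$delta_left
  shift[groups == "right", 2] <- config$delta_right
  shift[groups == "bilateral", ] <- config$delta_bilateral
  shift <- shift * vscale
  a_eff <- a - shift

  # planted category-selective cases among the patients
  planted <- rep("none", n)
  planted_delta <- rep(0, n)
  avail <- which(is_pat)
  for (p in config$planted_cases) {
    if (p$count == 0) next
    if (p$count > length(avail)) stop("not enough patients to plant cases")
    pick <- sample(avail, p$count)
    planted[pick] <- p$domain
    planted_delta[pick] <- p$delta
    avail <- setdiff(avail, pick)
  }

  zage <- (age - 61.5) / 14.6
  tvar <- implied_test_var(config)
  doms <- vapply(schema, `[[`, "", "domain")
  U <- a_eff %*% t(config$loading_table) +
    outer(zage, config$age_effect) +
    matrix(stats::rnorm(n * nt), n, nt) %*% diag(config$noise_sd)
  for (dom in c("word", "object", "face")) {
    rows <- which(planted == dom)
    if (!length(rows)) next
    cols <- which(doms == dom)
    U[rows, cols] <- U[rows, cols] -
      outer(planted_delta[rows], sqrt(tvar[cols]))
  }

  # map latent test scores to measures
  cols <- schema_columns(schema)
  values <- matrix(NA_real_, n, length(cols),
                   dimnames = list(ids, cols))
  rho <- config$within_test_cor
  for (ti in seq_len(nt)) {
    ts <- schema[[ti]]
    u <- U[, ti]
    if (nrow(ts$measures) == 1L) {
      values[, paste0(ts$test_id, "__", ts$measures$measure_id)] <-
        80 + 12 * u
    } else {
      # both measures share u; independent noise tuned so cor(acc, -rt) = rho
      tau <- sqrt(stats::var(u) * (1 - rho) / rho)
      for (j in seq_len(nrow(ts$measures))) {
        mid <- ts$measures$measure_id[j]
        v <- u + stats::rnorm(n, 0, tau)
        col <- paste0(ts$test_id, "__", mid)
        values[, col] <- if (identical(mid, "rt")) 800 - 150 * v else
          80 + 12 * v
      }
    }
  }

  observed <- matrix(stats::runif(length(values)) >= config$missing_rate,
                     n, length(cols), dimnames = dimnames(values))
  # keep every row and column analysable
  observed[rowSums(observed) == 0L, 1L] <- TRUE
  if (any(colSums(observed) == 0L))
    observed[1L, colSums(observed) == 0L] <- TRUE

  participants <- data.frame(
    participant_id = ids, group = groups, age = age, education = education,
    lesion_volume = lesion_volume, time_since_stroke = tss,
    stringsAsFactors = FALSE)
  masked <- values
  masked[!observed] <- NA_real_
  cohort <- cohort_table(participants, schema, masked, observed)
  truth <- list(
    participants = data.frame(
      participant_id = ids, group = groups, factor1 = a[, 1],
      factor2 = a[, 2], shift1 = shift[, 1], shift2 = shift[, 2],
      planted = planted, planted_delta = planted_delta,
      stringsAsFactors = FALSE),
    loading_table = config$loading_table,
    values_complete = values,
    config = config, seed = seed)
  structure(list(cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$cohort)
  np <- sum(x$truth$participants$planted != "none")
  if (np) cat(sprintf("  planted cases: %d\n", np))
  invisible(x)
}

#' Recovery metrics of a fitted case-series analysis against ground truth
#'
#' Compares a [case_series()] fit on a synthetic cohort with the generating
#' truth: per-domain sensitivity of planted cases recovered as
#' *domain-only* deficit patterns, the planted-vs-recovered label matrix,
#' the false-positive rate among unplanted patients, Tucker congruence of
#' the rotated loadings with the generating loadings, and (when the cohort
#' had missing cells) the imputation RMSE against a column-mean baseline.
#'
#' @param fit A [case_series()] object fitted to `truth`'s cohort.
#' @param truth The `truth` element of [generate_cohort()].
#' @return A list of class `recovery_report`.
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "case_series"))
  lab <- fit$patterns$labels
  tp <- truth$participants[truth$participants$group != "control", ]
  if (!setequal(lab$participant_id, tp$participant_id))
    stop("fit and truth participant ids do not match")
  m <- match(lab$participant_id, tp$participant_id)
  planted <- tp$planted[m]
  only <- c(word = "W", object = "O", face = "F")
  sens <- vapply(names(only), function(dom) {
    idx <- planted == dom
    if (!any(idx)) return(NA_real_)
    mean(lab$label[idx] == only[[dom]])
  }, 0)
  label_matrix <- table(planted = planted, recovered = lab$label)
  null_fp <- mean(lab$label[planted == "none"] != "NONE")
  congruence <- tucker_congruence(
    fit$solution$loadings,
    truth$loading_table[rownames(fit$solution$loadings), , drop = FALSE])

  imp_rmse <- baseline_rmse <- NA_real_
  miss <- !fit$observed_input
  if (any(miss)) {
    comp <- fit$values_imputed
    truev <- truth$values_complete
    imp_rmse <- sqrt(mean((comp[miss] - truev[miss])^2))
    xm <- truev
    xm[miss] <- NA_real_
    cm <- matrix(colMeans(xm, na.rm = TRUE), nrow(xm), ncol(xm),
                 byrow = TRUE)
    baseline_rmse <- sqrt(mean((cm[miss] - truev[miss])^2))
  }
  structure(list(sensitivity_domain_only = sens,
                 label_matrix = label_matrix,
                 null_false_positive_rate = null_fp,
                 loading_congruence = congruence,
                 imputation_rmse = imp_rmse,
                 column_mean_rmse = baseline_rmse),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat("  domain-only sensitivity:",
      paste(sprintf("%s %.2f", names(x$sensitivity_domain_only),
                    x$sensitivity_domain_only), collapse = ", "), "\n")
  cat(sprintf("  null false-positive rate: %.3f\n",
              x$null_false_positive_rate))
  cat("  loading congruence:",
      paste(sprintf("%.3f", x$loading_congruence), collapse = ", "), "\n")
  if (!is.na(x$imputation_rmse))
    cat(sprintf("  imputation RMSE %.3f vs column-mean %.3f\n",
                x$imputation_rmse, x$column_mean_rmse))
  invisible(x)
}
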