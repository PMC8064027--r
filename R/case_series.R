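#' Fit the full case-series analysis to a cohort
#'
#' Runs the complete analysis pipeline on a patient/control cohort:
#'
#' 1. **Imputation** — missing scores are completed by probabilistic PCA,
#'    fitted separately to patients and controls, with the component count
#'    chosen by cross-validation ([impute_cohort()]).
#' 2. **Preprocessing** — response-time measures are negated so all scores
#'    are higher-is-better, multi-measure tests are collapsed to their first
#'    principal component ([orient_measures()], [collapse_test_measures()]).
#' 3. **Group PCA** — the patient score matrix, z-scored to the patient
#'    group, is eigen-decomposed; components with eigenvalue > 1 are
#'    retained, varimax-rotated, and scored by the regression method; the
#'    control norms and the impairment cutoff (control mean minus two
#'    control SDs per factor) are projected into the same space
#'    ([extract_components()], [rotate_varimax()], [project_controls()]).
#' 4. **Composite scores** — one composite per domain (word, object, face)
#'    over controls and patients ([composite_scores()]).
#' 5. **Single-case classification** — per-patient Bayesian deficit tests
#'    with age as covariate, deficit-pattern labels, and pairwise
#'    dissociation tests gated on at least one deficit
#'    ([deficit_tests()], [pattern_table()], [dissociation_tests()]).
#'
#' Every stochastic stage receives a seed derived deterministically from
#' `seed`, so refitting with the same inputs reproduces the result exactly.
#'
#' @param cohort A [cohort_table].
#' @param covariates Covariates for the single-case tests (default
#'   `"age"`).
#' @param alpha Significance level for deficit and dissociation flags.
#' @param n_mc Monte-Carlo draws per single-case test.
#' @param k_grid,folds,repetitions Settings for the imputation
#'   cross-validation.
#' @param cutoff_mode Cutoff construction, see [project_controls()].
#' @param composite_method `"pca_weighted"` or `"rank_sum"`.
#' @param tail_deficit,tail_diff Tails of the deficit and difference tests.
#' @param collapse_rows Rows defining the measure-collapsing weights for
#'   the group PCA: `"patients"` (default) or `"all"`.
#' @param seed Master seed.
#' @return An object of class `case_series` with components `cv`,
#'   `solution` (the rotated [extract_components()] result), `factor_scores`
#'   (with control projection and cutoffs), `composites`, `deficits`,
#'   `patterns`, `dissociations`, `overlay`, and bookkeeping fields.
#' @export
case_series <- function(cohort, covariates = "age", alpha = 0.05,
                        n_mc = 10000L, k_grid = 1:5, folds = 5L,
                        repetitions = 5L,
                        cutoff_mode = c("score_sd",
                                        "projected_pseudosubject"),
                        composite_method = c("pca_weighted", "rank_sum"),
                        tail_deficit = "lower", tail_diff = "two",
                        collapse_rows = c("patients", "all"),
                        seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"), alpha > 0, alpha < 1)
  cutoff_mode <- match.arg(cutoff_mode)
  composite_method <- match.arg(composite_method)
  collapse_rows <- match.arg(collapse_rows)
  assert_analysable(cohort)
  seeds <- seed + seq_len(8L) * 101L          # counter-based fan-out

  observed_input <- cohort$observed
  imp <- impute_cohort(cohort, k_grid = k_grid, folds = folds,
                       repetitions = repetitions, seed = seeds[1L])
  completed <- imp$cohort
  values_imputed <- completed$values

  oriented <- orient_measures(completed)
  sm_pat <- collapse_test_measures(oriented, rows = collapse_rows)
  # restrict PCA fitting rows to patients even when the plan uses all rows
  grp <- oriented$participants$group
  if (collapse_rows == "all") {
    sm_fit <- sm_pat
    sm_fit$values <- sm_fit$values[grp != "control", , drop = FALSE]
    sm_fit$groups <- droplevels(grp[grp != "control"])
  } else sm_fit <- sm_pat
  Zp <- zscore_to_reference(sm_fit, reference = "all")

  solution <- rotate_varimax(extract_components(Zp))
  fs <- factor_scores(solution, Zp)
  rownames(fs$scores) <- rownames(Zp$values)
  ctrl_sm <- apply_collapse(oriented, sm_pat$plan, rows = "controls")
  Zc <- zscore_apply(ctrl_sm, Zp$reference)
  fs <- project_controls(fs, solution, Zc, cutoff_mode = cutoff_mode)

  sm_all <- collapse_test_measures(oriented, rows = "all")
  comps <- composite_scores(sm_all, oriented$schema,
                            method = composite_method)
  deficits <- deficit_tests(comps, oriented, covariates = covariates,
                            alpha = alpha, tail = tail_deficit,
                            n_mc = n_mc, seed = seeds[2L])
  patterns <- pattern_table(deficits, oriented)
  dissociations <- dissociation_tests(comps, oriented, deficits,
                                      covariates = covariates,
                                      alpha = alpha, tail = tail_diff,
                                      n_mc = n_mc, seed = seeds[3L])
  overlay <- overlay_report(fs, patterns, oriented)

  structure(list(cohort = cohort, cv = imp$cv, ppca_models = imp$models,
                 observed_input = observed_input,
                 values_imputed = values_imputed,
                 solution = solution, factor_scores = fs,
                 composites = comps, deficits = deficits,
                 patterns = patterns, dissociations = dissociations,
                 overlay = overlay,
                 settings = list(covariates = covariates, alpha = alpha,
                                 n_mc = n_mc, cutoff_mode = cutoff_mode,
                                 composite_method = composite_method,
                                 tail_deficit = tail_deficit,
                                 tail_diff = tail_diff,
                                 collapse_rows = collapse_rows,
                                 seed = seed)),
            class = "case_series")
}

#' @export
print.case_series <- function(x, ...) {
  cat("Case-series analysis\n")
  tab <- table(x$cohort$participants$group)
  cat(sprintf("  cohort: %s\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  cat(sprintf("  PCA: %d factor(s), %.0f%% variance explained, KMO = %.3f\n",
              x$solution$n_retained, 100 * x$solution$total_var_explained,
              x$solution$kmo))
  cnt <- table(x$patterns$labels$label)
  cnt <- cnt[cnt > 0]
  cat(sprintf("  deficit patterns: %s\n",
              paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")))
  n_cls <- sum(x$dissociations$label == "classical")
  n_dif <- sum(x$dissociations$label == "differential")
  cat(sprintf("  dissociations: %d classical, %d differential\n",
              n_cls, n_dif))
  invisible(x)
}

#' @export
summary.case_series <- function(object, ...) {
  structure(list(fit = object), class = "summary.case_series")
}

#' @export
print.summary.case_series <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nEigenvalues:",
      paste(sprintf("%.2f", f$solution$eigenvalues[
        seq_len(min(6, length(f$solution$eigenvalues)))]), collapse = ", "),
      "...\n")
  cat("\nRotated loadings:\n")
  print(round(f$solution$loadings, 2))
  cat("\nControl projection: mean ",
      paste(sprintf("%.2f", f$factor_scores$control_mean), collapse = ", "),
      "; cutoff ",
      paste(sprintf("%.2f", f$factor_scores$cutoff), collapse = ", "),
      "\n", sep = "")
  cat("\nDeficit pattern counts by laterality:\n")
  print(f$patterns$counts)
  invisible(x)
}

#' @export
coef.case_series <- function(object, ...) object$solution$loadings

#' Plot a fitted case-series analysis
#'
#' Scatter of patient scores on the first two factors, coloured by lesion
#' laterality, filled by deficit-pattern label, with the control mean
#' (solid) and the two-SD impairment cutoff (dashed) on each factor.
#'
#' @param x A [case_series()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.case_series <- function(x, ...) {
  ov <- x$overlay
  if (!"factor2" %in% names(ov)) {
    graphics::plot(ov$factor1, rep(0, nrow(ov)), xlab = "Factor 1",
                   ylab = "", yaxt = "n", ...)
    graphics::abline(v = x$factor_scores$control_mean[1])
    graphics::abline(v = x$factor_scores$cutoff[1], lty = 2)
    return(invisible(x))
  }
  side_col <- c(left = "blue3", right = "red3", bilateral = "purple3")
  fill <- c(NONE = "white", W = "cyan", O = "orange", F = "magenta",
            WO = "green3", WF = "yellow", OF = "pink", WOF = "grey30")
  graphics::plot(ov$factor1, ov$factor2, pch = 21,
                 bg = fill[ov$pattern], col = side_col[ov$laterality],
                 lwd = 2, xlab = "Factor 1 (word/object)",
                 ylab = "Factor 2 (face/object)",
                 cex = 0.8 + sqrt(pmax(ov$lesion_volume, 0)) / 8, ...)
  graphics::abline(v = x$factor_scores$control_mean[1],
                   h = x$factor_scores$control_mean[2])
  graphics::abline(v = x$factor_scores$cutoff[1],
                   h = x$factor_scores$cutoff[2], lty = 2)
  invisible(x)
}

#' Collect a fitted analysis into a writable result bundle
#'
#' @param fit A [case_series()] fit.
#' @return Named list of data frames suitable for [write_results()]:
#'   loadings, factor scores, composites, deficit table, pattern counts,
#'   dissociation table and overlay.
#' @export
result_bundle <- function(fit) {
  stopifnot(inherits(fit, "case_series"))
  sol <- fit$solution
  loadings <- data.frame(test_id = rownames(sol$loadings),
                         as.data.frame(sol$loadings), check.names = FALSE)
  sc <- fit$factor_scores$scores
  scores <- data.frame(participant_id = rownames(sc),
                       as.data.frame(sc), check.names = FALSE)
  comp <- data.frame(
    participant_id = rownames(fit$composites$scores),
    as.data.frame(fit$composites$scores), check.names = FALSE)
  counts <- as.data.frame(fit$patterns$counts)
  list(loadings = loadings, factor_scores = scores, composites = comp,
       deficits = as.data.frame(fit$deficits),
       pattern_counts = counts,
       dissociations = as.data.frame(fit$dissociations),
       overlay = fit$overlay)
}
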