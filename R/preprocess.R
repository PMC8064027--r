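#' Orient all measures so that higher scores mean better performance
#'
#' Measures declared `lower_is_better` (response times) are negated and their
#' direction rewritten to `higher_is_better`; the observedness mask is
#' untouched. Because directions are rewritten, a second call is a no-op.
#'
#' @param cohort A [cohort_table].
#' @return The reoriented [cohort_table].
#' @export
orient_measures <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  col <- 0L
  for (i in seq_along(cohort$schema)) {
    ts <- cohort$schema[[i]]
    for (j in seq_len(nrow(ts$measures))) {
      col <- col + 1L
      dir <- ts$measures$direction[j]
      if (is.na(dir))
        stop("test '", ts$test_id, "', measure '", ts$measures$measure_id[j],
             "': direction undeclared")
      if (dir == "lower_is_better") {
        cohort$values[, col] <- -cohort$values[, col]
        cohort$schema[[i]]$measures$direction[j] <- "higher_is_better"
      }
    }
  }
  cohort
}

#' A per-test score matrix
#'
#' Internal container produced by [collapse_test_measures()]: one column per
#' test (multi-measure tests collapsed to their first principal component),
#' uniformly oriented higher-is-better, with the collapse plan attached so
#' new rows (e.g. controls) can be mapped through the same transformation,
#' and reference statistics recorded by [zscore_to_reference()].
#'
#' @param values Numeric matrix, rows = participants, cols = tests.
#' @param groups Factor of group labels aligned with rows.
#' @param plan Collapse plan (see [collapse_test_measures()]).
#' @param reference Reference statistics, or `NULL`.
#' @return An object of class `score_matrix`.
#' @keywords internal
score_matrix <- function(values, groups, plan = NULL, reference = NULL) {
  structure(list(values = values, groups = groups, plan = plan,
                 reference = reference), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d participants x %d tests%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$reference))
                paste0(", z-scored to ", x$reference$group) else ""))
  invisible(x)
}

#' Collapse multi-measure tests to one column per test
#'
#' For every test with several measures the measures are column-standardised
#' over the included rows and replaced by scores on the first unrotated
#' principal component of their correlation matrix, sign-fixed so that the
#' accuracy measure loads positively and rescaled to unit variance.
#' Single-measure tests pass through as z-scores. Requires a fully observed
#' matrix (run after imputation).
#'
#' @param cohort A [cohort_table], already oriented via [orient_measures()].
#' @param rows Row selector: `"all"`, `"patients"`, `"controls"`, or a
#'   logical/integer index. Standardisation and component weights are
#'   computed over these rows only.
#' @return A [score_matrix] for the selected rows with the collapse plan
#'   attached (per-test measure means, SDs and weights), reusable on held-out
#'   rows via [apply_collapse()].
#' @export
collapse_test_measures <- function(cohort, rows = "all") {
  stopifnot(inherits(cohort, "cohort_table"))
  idx <- resolve_rows(cohort, rows)
  if (length(idx) < 2L) stop("collapsing requires at least 2 participants")
  vals <- cohort$values[idx, , drop = FALSE]
  if (anyNA(vals))
    stop("missing entries present; impute before collapsing measures")
  plan <- list()
  for (ts in cohort$schema) {
    cols <- paste(ts$test_id, ts$measures$measure_id, sep = "__")
    m <- vals[, cols, drop = FALSE]
    mu <- colMeans(m)
    sd_ <- apply(m, 2, stats::sd)
    if (any(sd_ == 0))
      stop("zero-variance measure: ",
           paste(cols[sd_ == 0], collapse = ", "))
    z <- sweep(sweep(m, 2, mu), 2, sd_, "/")
    if (ncol(z) == 1L) {
      w <- 1
      sc <- 1
    } else {
      e <- eigen(stats::cor(z), symmetric = TRUE)
      w <- e$vectors[, 1]
      acc <- match("accuracy", ts$measures$measure_id, nomatch = 1L)
      if (w[acc] < 0) w <- -w
      sc <- stats::sd(drop(z %*% w))
    }
    plan[[ts$test_id]] <- list(columns = cols, mean = mu, sd = sd_,
                               weights = w, scale = sc)
  }
  sm <- apply_collapse(cohort, plan, rows = idx)
  sm
}

#' Map rows of a cohort through an existing collapse plan
#'
#' @param cohort A [cohort_table] (oriented, fully observed on the selected
#'   rows).
#' @param plan Collapse plan from [collapse_test_measures()] (the `plan`
#'   element of its result).
#' @param rows Row selector as in [collapse_test_measures()].
#' @return A [score_matrix] whose columns use the plan's standardisation and
#'   component weights.
#' @export
apply_collapse <- function(cohort, plan, rows = "all") {
  idx <- resolve_rows(cohort, rows)
  vals <- cohort$values[idx, , drop = FALSE]
  if (anyNA(vals))
    stop("missing entries present; impute before collapsing measures")
  out <- matrix(NA_real_, nrow(vals), length(plan),
                dimnames = list(rownames(vals), names(plan)))
  for (tid in names(plan)) {
    pl <- plan[[tid]]
    z <- sweep(sweep(vals[, pl$columns, drop = FALSE], 2, pl$mean),
               2, pl$sd, "/")
    out[, tid] <- drop(z %*% pl$weights) / pl$scale
  }
  score_matrix(out, droplevels(cohort$participants$group[idx]), plan = plan)
}

resolve_rows <- function(cohort, rows) {
  grp <- cohort$participants$group
  if (is.character(rows) && length(rows) == 1L &&
      rows %in% c("all", "patients", "controls")) {
    idx <- switch(rows, all = seq_along(grp),
                  patients = which(grp != "control"),
                  controls = which(grp == "control"))
  } else if (is.logical(rows)) {
    stopifnot(length(rows) == length(grp))
    idx <- which(rows)
  } else {
    idx <- as.integer(rows)
    stopifnot(all(idx >= 1L), all(idx <= length(grp)))
  }
  idx
}

#' Standardise a score matrix against a reference group
#'
#' Every column is transformed by `(x - mean_ref) / sd_ref`, where the
#' reference statistics are computed over the selected reference rows.
#' The reference identity and per-column statistics are recorded so the same
#' transform can be applied to held-out rows.
#'
#' @param sm A [score_matrix].
#' @param reference `"all"`, `"patients"` or `"controls"` (rows of `sm` by
#'   their group label), or a logical/integer row index into `sm`.
#' @return The standardised [score_matrix], with `reference` recorded.
#' @export
zscore_to_reference <- function(sm, reference = "all") {
  stopifnot(inherits(sm, "score_matrix"))
  grp <- sm$groups
  if (is.character(reference) && length(reference) == 1L) {
    ridx <- switch(reference,
                   all = seq_len(nrow(sm$values)),
                   patients = which(grp != "control"),
                   controls = which(grp == "control"),
                   stop("unknown reference: ", reference))
    rname <- reference
  } else if (is.logical(reference)) {
    ridx <- which(reference); rname <- "custom"
  } else {
    ridx <- as.integer(reference); rname <- "custom"
  }
  if (length(ridx) < 2L) stop("reference subgroup needs >= 2 members")
  mu <- colMeans(sm$values[ridx, , drop = FALSE])
  sd_ <- apply(sm$values[ridx, , drop = FALSE], 2, stats::sd)
  if (any(sd_ == 0))
    stop("reference sd is zero for column(s): ",
         paste(colnames(sm$values)[sd_ == 0], collapse = ", "))
  sm$values <- sweep(sweep(sm$values, 2, mu), 2, sd_, "/")
  sm$reference <- list(group = rname, mean = mu, sd = sd_)
  sm
}

# apply recorded reference statistics to another score matrix
zscore_apply <- function(sm, reference) {
  sm$values <- sweep(sweep(sm$values, 2, reference$mean), 2,
                     reference$sd, "/")
  sm$reference <- reference
  sm
}
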