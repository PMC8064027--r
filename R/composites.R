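#' Domain composite scores for words, objects and faces
#'
#' Builds one composite per domain from the tests flagged `in_composite` in
#' the schema. With `method = "pca_weighted"` each domain's tests are
#' standardised over all included subjects (controls and patients) and
#' scored on their first unrotated principal component, sign-fixed so the
#' mean loading is positive (higher = better) and standardised to mean 0,
#' SD 1 over the fitting sample. With `method = "rank_sum"` each test is
#' ranked over all subjects (mean rank for ties, higher = better) and ranks
#' are averaged within the domain.
#'
#' @param sm A [score_matrix] over controls and patients (fully observed,
#'   oriented, collapsed to one column per test).
#' @param schema Named list of [test_spec] objects; its `in_composite` flags
#'   define the domain -> test mapping.
#' @param method `"pca_weighted"` (default) or `"rank_sum"`.
#' @return An object of class `composite_scores`: an n x 3 matrix of word,
#'   object and face composites plus per-domain loading (or rank) tables.
#' @export
composite_scores <- function(sm, schema, method = c("pca_weighted",
                                                    "rank_sum")) {
  method <- match.arg(method)
  stopifnot(inherits(sm, "score_matrix"))
  M <- sm$values
  if (anyNA(M)) stop("missing entries present; impute first")
  domains <- c("word", "object", "face")
  comp <- matrix(NA_real_, nrow(M), 3,
                 dimnames = list(rownames(M), domains))
  info <- list()
  for (dom in domains) {
    tests <- names(schema)[vapply(schema, function(ts)
      ts$in_composite && ts$domain == dom, TRUE)]
    if (!length(tests)) stop("no composite tests for domain ", dom)
    sub <- M[, tests, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (all(sds == 0)) stop("all tests in domain ", dom, " are constant")
    if (method == "pca_weighted") {
      if (any(sds == 0))
        stop("zero-variance test in domain ", dom, ": ",
             paste(tests[sds == 0], collapse = ", "))
      z <- scale(sub)
      if (ncol(z) == 1L) {
        w <- 1
        sc <- drop(z)
      } else {
        e <- eigen(stats::cor(z), symmetric = TRUE)
        w <- e$vectors[, 1]
        if (mean(w) < 0) w <- -w
        sc <- drop(z %*% w)
      }
      sc <- (sc - mean(sc)) / stats::sd(sc)
      comp[, dom] <- sc
      info[[dom]] <- data.frame(test_id = tests, loading = w,
                                stringsAsFactors = FALSE)
    } else {
      rk <- apply(sub, 2, rank)            # mean rank for ties
      comp[, dom] <- rowMeans(rk)
      info[[dom]] <- data.frame(test_id = tests, stringsAsFactors = FALSE)
    }
  }
  structure(list(scores = comp, method = method, tables = info,
                 groups = sm$groups), class = "composite_scores")
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("<composite_scores> %d participants, method = %s\n",
              nrow(x$scores), x$method))
  invisible(x)
}

#' Per-patient deficit tests on the domain composites
#'
#' Runs [btd_cov()] once per patient and domain, comparing each patient's
#' composite to the control composites with the requested covariates
#' (age by default, since control performance declines with age).
#'
#' @param comps A [composite_scores] object over controls and patients.
#' @param cohort The matching [cohort_table] (for covariates and groups).
#' @param covariates Character vector of participant columns to condition
#'   on; default `"age"`.
#' @param alpha Significance level for the deficit flag.
#' @param tail Tail for the deficit test (default `"lower"`).
#' @param n_mc,seed Monte-Carlo settings; per-test seeds derive from `seed`.
#' @return A data frame of class `deficit_table`: one row per
#'   patient x domain with p, abnormality percentage, credible interval,
#'   effect size and the deficit flag (`p < alpha`).
#' @export
deficit_tests <- function(comps, cohort, covariates = "age", alpha = 0.05,
                          tail = "lower", n_mc = 10000L, seed = NULL) {
  stopifnot(inherits(comps, "composite_scores"),
            inherits(cohort, "cohort_table"))
  assert_analysable(cohort)
  pp <- cohort$participants
  if (!identical(rownames(comps$scores), pp$participant_id))
    stop("composite rows do not match the cohort's participants")
  ctrl <- pp$group == "control"
  X <- covariate_matrix(pp, covariates)
  pats <- which(!ctrl)
  out <- vector("list", length(pats) * 3L)
  i <- 0L
  for (pi in pats) {
    for (dom in colnames(comps$scores)) {
      i <- i + 1L
      r <- btd_cov(y = comps$scores[ctrl, dom],
                   y_star = comps$scores[pi, dom],
                   X = if (is.null(X)) NULL else X[ctrl, , drop = FALSE],
                   x_star = if (is.null(X)) NULL else X[pi, ],
                   tail = tail, n_mc = n_mc,
                   seed = if (is.null(seed)) NULL else seed + i)
      out[[i]] <- data.frame(
        participant_id = pp$participant_id[pi], domain = dom,
        p = r$p, abnormality_pct = r$abnormality_pct,
        ci_lower = r$ci[1], ci_upper = r$ci[2], z_ccc = r$z_ccc,
        deficit = r$p < alpha, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "tail") <- tail
  class(res) <- c("deficit_table", "data.frame")
  res
}

covariate_matrix <- function(pp, covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(pp))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(pp[, covariates, drop = FALSE])
  if (anyNA(X))
    stop("missing covariate values for participant(s): ",
         paste(pp$participant_id[apply(is.na(X), 1, any)], collapse = ", "))
  X
}

deficit_flags <- function(deficits) {
  wide <- stats::reshape(
    deficits[, c("participant_id", "domain", "deficit")],
    idvar = "participant_id", timevar = "domain", direction = "wide")
  names(wide) <- sub("^deficit\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Classify per-patient deficit patterns
#'
#' Maps each patient's (word, object, face) deficit flags to one of eight
#' pattern labels (`NONE`, `W`, `O`, `F`, `WO`, `WF`, `OF`, `WOF`) and
#' tabulates label frequencies by lesion laterality.
#'
#' @param deficits A [deficit_tests()] table.
#' @param cohort The matching [cohort_table].
#' @return A list of class `deficit_pattern`: `labels` (one row per patient
#'   with flags and label) and `counts` (label x laterality frequency
#'   table; counts sum to the number of patients).
#' @export
pattern_table <- function(deficits, cohort) {
  flags <- deficit_flags(deficits)
  lab <- apply(flags[, c("word", "object", "face")], 1, function(f) {
    s <- paste0(if (f[["word"]]) "W" else "", if (f[["object"]]) "O" else "",
                if (f[["face"]]) "F" else "")
    if (s == "") "NONE" else s
  })
  levs <- c("NONE", "W", "O", "F", "WO", "WF", "OF", "WOF")
  labels <- data.frame(participant_id = flags$participant_id,
                       word = flags$word, object = flags$object,
                       face = flags$face,
                       label = factor(lab, levels = levs),
                       stringsAsFactors = FALSE)
  m <- match(labels$participant_id, cohort$participants$participant_id)
  if (anyNA(m)) stop("deficit table and cohort ids do not match")
  labels$laterality <- droplevels(cohort$participants$group[m])
  counts <- table(label = labels$label, laterality = labels$laterality)
  structure(list(labels = labels, counts = counts),
            class = "deficit_pattern")
}

#' @export
print.deficit_pattern <- function(x, ...) {
  cat("<deficit_pattern> counts by laterality:\n")
  print(x$counts)
  invisible(x)
}

#' Pairwise dissociation tests between domains
#'
#' For every patient with at least one significant domain deficit, tests
#' each domain pair for a dissociation. A *classical* dissociation requires
#' (1) a significant deficit on task X, (2) task Y within the control range
#' (deficit-test p >= alpha), and (3) a significant standardised difference
#' between X and Y ([bsdt_cov()], with covariates). When both tasks are
#' individually impaired but the standardised difference is significant the
#' pair is labelled a *differential* (strong) dissociation.
#'
#' @param comps A [composite_scores] object.
#' @param cohort The matching [cohort_table].
#' @param deficits The [deficit_tests()] table (supplies criteria 1 and 2
#'   and the gating).
#' @param pairs List of 2-element character vectors of domains; default all
#'   three pairs.
#' @param covariates,alpha,n_mc,seed As in [deficit_tests()].
#' @param tail Tail for the difference test (default `"two"`).
#' @return A data frame of class `dissociation_table`: one row per gated
#'   patient x pair with the three criteria and the label
#'   (`none`/`classical`/`differential`).
#' @export
dissociation_tests <- function(comps, cohort, deficits,
                               pairs = list(c("word", "face"),
                                            c("word", "object"),
                                            c("object", "face")),
                               covariates = "age", alpha = 0.05,
                               tail = "two", n_mc = 10000L, seed = NULL) {
  stopifnot(inherits(comps, "composite_scores"))
  pp <- cohort$participants
  ctrl <- pp$group == "control"
  X <- covariate_matrix(pp, covariates)
  flags <- deficit_flags(deficits)
  gated <- flags$participant_id[rowSums(
    flags[, c("word", "object", "face")]) > 0]
  out <- list(); i <- 0L
  for (pid in gated) {
    pi <- match(pid, pp$participant_id)
    frow <- flags[flags$participant_id == pid, ]
    for (pr in pairs) {
      i <- i + 1L
      fx <- frow[[pr[1]]]; fy <- frow[[pr[2]]]
      # orient the pair so X is the (more) impaired task
      if (!fx && fy) pr <- rev(pr)
      fx <- frow[[pr[1]]]; fy <- frow[[pr[2]]]
      r <- bsdt_cov(Y = comps$scores[ctrl, pr, drop = FALSE],
                    y_star = comps$scores[pi, pr],
                    X = if (is.null(X)) NULL else X[ctrl, , drop = FALSE],
                    x_star = if (is.null(X)) NULL else X[pi, ],
                    tail = tail, n_mc = n_mc,
                    seed = if (is.null(seed)) NULL else seed + i)
      c1 <- fx
      c2 <- !fy
      c3 <- r$p_diff < alpha
      label <- if (c1 && c2 && c3) "classical"
               else if (c1 && !c2 && c3) "differential"
               else "none"
      out[[i]] <- data.frame(
        participant_id = pid, task_x = pr[1], task_y = pr[2],
        criterion1_x_deficit = c1, criterion2_y_in_range = c2,
        criterion3_difference = c3, p_diff = r$p_diff,
        z_x = r$z_x, z_y = r$z_y, rho = r$rho, label = label,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(), task_x = character(),
               task_y = character(), criterion1_x_deficit = logical(),
               criterion2_y_in_range = logical(),
               criterion3_difference = logical(), p_diff = numeric(),
               z_x = numeric(), z_y = numeric(), rho = numeric(),
               label = character(), stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  class(res) <- c("dissociation_table", "data.frame")
  res
}

#' Join factor scores and deficit patterns for the overlay view
#'
#' One row per patient combining the data-driven factor scores (with
#' below-cutoff flags) and the composite-score deficit pattern, for
#' comparing the two analyses.
#'
#' @param fs A [factor_scores] object with cutoffs (after
#'   [project_controls()]).
#' @param patterns A [pattern_table()] result.
#' @param cohort The matching [cohort_table].
#' @return Data frame: factor scores, laterality, lesion volume, pattern
#'   label and per-factor below-cutoff flags.
#' @export
overlay_report <- function(fs, patterns, cohort) {
  stopifnot(inherits(fs, "factor_scores"),
            inherits(patterns, "deficit_pattern"))
  if (is.null(fs$cutoff)) stop("factor scores carry no cutoffs; run project_controls()")
  ids <- rownames(fs$scores)
  lab <- patterns$labels
  if (!setequal(ids, lab$participant_id))
    stop("factor-score and pattern participant ids do not match")
  m <- match(ids, lab$participant_id)
  mc <- match(ids, cohort$participants$participant_id)
  out <- data.frame(participant_id = ids,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(fs$scores))) {
    out[[paste0("factor", j)]] <- fs$scores[, j]
    out[[paste0("below_cutoff_f", j)]] <- fs$scores[, j] < fs$cutoff[j]
  }
  out$laterality <- as.character(cohort$participants$group[mc])
  out$lesion_volume <- cohort$participants$lesion_volume[mc]
  out$pattern <- as.character(lab$label[m])
  rownames(out) <- NULL
  out
}
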