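# shared small synthetic fit kept light; built once per file
fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_cohort(
        null_config(planted_cases = list(list(domain = "word", delta = 4,
                                              count = 2))),
        seed = 404)
      cache <<- list(
        g = g,
        fit = case_series(g$cohort, n_mc = 4000, repetitions = 1,
                          k_grid = 1:2, seed = 11))
    }
    cache
  }
})

test_that("composite scores are standardised weighted averages per domain", {
  g <- generate_cohort(cohort_config(missing_rate = 0), seed = 51)
  co <- orient_measures(g$cohort)
  sm <- collapse_test_measures(co, rows = "all")
  cs <- composite_scores(sm, co$schema)
  expect_equal(unname(colMeans(cs$scores)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(cs$scores, 2, sd)), rep(1, 3),
               tolerance = 1e-8)
  # positive mean loading per domain (higher = better)
  for (tab in cs$tables) expect_gt(mean(tab$loading), 0)
})

test_that("composite scores match an eigen-decomposition oracle", {
  set.seed(52)
  n <- 20
  z <- matrix(rnorm(n), n, 4) * 0.8 + matrix(rnorm(4 * n, 0, .5), n)
  sm <- caseseries:::score_matrix(
    `colnames<-`(z, c("delayed_match_words", "surprise_recog_words",
                      "lexical_decision", "word_reading")),
    factor(rep("control", n), levels = c("control", "left")))
  # a schema restricted to the word domain
  schema <- vot_battery()[c("delayed_match_words", "surprise_recog_words",
                            "lexical_decision", "word_reading")]
  # pad score matrix with the object/face composite tests to satisfy domains
  full <- vot_battery()
  smf <- caseseries:::score_matrix(
    matrix(rnorm(n * 22), n, dimnames = list(NULL, names(full))),
    sm$groups)
  smf$values[, colnames(sm$values)] <- sm$values
  cs <- composite_scores(smf, full)
  # oracle: first eigenvector of the 4x4 correlation matrix
  zz <- scale(sm$values)
  e <- eigen(cor(zz), symmetric = TRUE)
  w <- e$vectors[, 1]; if (mean(w) < 0) w <- -w
  oracle <- drop(zz %*% w)
  oracle <- (oracle - mean(oracle)) / sd(oracle)
  expect_equal(unname(cs$scores[, "word"]), oracle, tolerance = 1e-10)
})

test_that("rank composites are order-isomorphic to mean per-test ranks", {
  g <- generate_cohort(cohort_config(missing_rate = 0), seed = 53)
  co <- orient_measures(g$cohort)
  sm <- collapse_test_measures(co, rows = "all")
  cs <- composite_scores(sm, co$schema, method = "rank_sum")
  word_tests <- names(co$schema)[vapply(co$schema, function(ts)
    ts$in_composite && ts$domain == "word", TRUE)]
  manual <- rowMeans(apply(sm$values[, word_tests], 2, rank))
  expect_identical(order(cs$scores[, "word"]), order(manual))
})

test_that("pattern labels partition patients over the eight classes", {
  fx <- fixture_fit()
  pt <- fx$fit$patterns
  expect_identical(sum(pt$counts), caseseries::n_patients(fx$g$cohort))
  expect_identical(nrow(pt$labels), caseseries::n_patients(fx$g$cohort))
  expect_true(all(levels(pt$labels$label) ==
                    c("NONE", "W", "O", "F", "WO", "WF", "OF", "WOF")))
  # label is the deterministic image of the flags
  with(pt$labels, {
    expect_identical(label == "WOF", word & object & face)
    expect_identical(label == "NONE", !word & !object & !face)
    expect_identical(label == "W", word & !object & !face)
  })
})

test_that("deficit tests flag planted cases and spare null patients", {
  fx <- fixture_fit()
  lab <- fx$fit$patterns$labels
  tp <- fx$g$truth$participants
  planted <- tp$participant_id[tp$planted == "word"]
  flagged <- lab[match(planted, lab$participant_id), ]
  expect_true(all(flagged$word))
  # planted word cases are never face-selective
  expect_false(any(flagged$label == "F"))
  nulls <- lab[lab$participant_id %in%
                 tp$participant_id[tp$planted == "none"], ]
  expect_lt(mean(nulls$label != "NONE"), 0.25)
})

test_that("classical dissociations require all three criteria", {
  fx <- fixture_fit()
  ds <- fx$fit$dissociations
  expect_true(all(ds$label[ds$label == "classical"] ==
                    ifelse(ds$criterion1_x_deficit[ds$label == "classical"] &
                             ds$criterion2_y_in_range[ds$label == "classical"] &
                             ds$criterion3_difference[ds$label == "classical"],
                           "classical", "impossible")))
  # structurally impossible: classical with criterion 2 failing
  expect_false(any(ds$label == "classical" & !ds$criterion2_y_in_range))
  # gating: every tested patient has at least one deficit flag
  flags <- caseseries:::deficit_flags(fx$fit$deficits)
  tested <- unique(ds$participant_id)
  gated <- flags$participant_id[rowSums(flags[, c("word", "object",
                                                  "face")]) > 0]
  expect_true(all(tested %in% gated))
  # planted cases show the word dissociation
  tp <- fx$g$truth$participants
  planted <- tp$participant_id[tp$planted == "word"]
  dsp <- ds[ds$participant_id %in% planted & ds$task_x == "word", ]
  expect_gt(mean(dsp$label == "classical"), 0.5)
})

test_that("an associated double deficit is not a dissociation", {
  set.seed(61)
  n <- 46
  Y <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, .6, .6, 1), 2))
  z <- -4
  ys <- c(mean(Y[, 1]) + z * sd(Y[, 1]), mean(Y[, 2]) + z * sd(Y[, 2]))
  r <- bsdt_cov(Y, ys, n_mc = 10000, seed = 2)
  expect_gt(r$p_diff, 0.05)
})

test_that("the overlay joins factor scores with patterns per patient", {
  fx <- fixture_fit()
  ov <- fx$fit$overlay
  expect_identical(nrow(ov), caseseries::n_patients(fx$g$cohort))
  expect_true(all(c("factor1", "factor2", "below_cutoff_f1", "laterality",
                    "lesion_volume", "pattern") %in% names(ov)))
  expect_identical(
    unname(ov$below_cutoff_f1),
    unname(ov$factor1 < fx$fit$factor_scores$cutoff[1]))
  # id mismatch errors
  bad <- fx$fit$patterns
  bad$labels$participant_id[1] <- "GHOST"
  expect_error(overlay_report(fx$fit$factor_scores, bad, fx$g$cohort),
               "ids do not match")
})
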