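# Small in-code fixtures shared across the suite.

# two-test schema: one single-measure test, one accuracy+RT test
tiny_schema <- function() {
  specs <- list(
    test_spec("naming", "object", "accuracy", in_composite = TRUE),
    test_spec("decision", "word",
              data.frame(measure_id = c("accuracy", "rt"),
                         direction = c("higher_is_better",
                                       "lower_is_better")),
              in_composite = TRUE))
  names(specs) <- vapply(specs, `[[`, "", "test_id")
  specs
}

# hand-built cohort over tiny_schema(): nc controls + np patients
tiny_cohort <- function(nc = 4, np = 3, seed = 1) {
  schema <- tiny_schema()
  n <- nc + np
  set.seed(seed)
  grp <- c(rep("control", nc), rep(c("left", "right", "bilateral"),
                                   length.out = np))
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    group = grp, age = round(runif(n, 40, 80)),
    education = round(runif(n, 10, 18)),
    lesion_volume = ifelse(grp == "control", NA, runif(n, 5, 60)),
    time_since_stroke = ifelse(grp == "control", NA, runif(n, 9, 80)),
    stringsAsFactors = FALSE)
  values <- cbind(
    naming__accuracy = rnorm(n, 80, 5),
    decision__accuracy = rnorm(n, 75, 8),
    decision__rt = rnorm(n, 800, 90))
  cohort_table(participants, schema, values)
}

# low-rank matrix with optional noise and MCAR mask
lowrank_matrix <- function(n, d, k, noise_sd = 0, missing = 0, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * k), n)
  L <- matrix(rnorm(d * k, sd = 1), d)
  x <- z %*% t(L) + matrix(rnorm(n * d, 0, noise_sd), n)
  if (missing > 0) {
    mask <- matrix(runif(n * d) < missing, n, d)
    # never blank out a full row/column
    mask[rowSums(!mask) == 0, 1] <- FALSE
    x[mask] <- NA
  }
  x
}

# default synthetic generator config with no lesion effects (null background)
null_config <- function(...) {
  cohort_config(delta_left = 0, delta_right = 0, delta_bilateral = 0, ...)
}
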