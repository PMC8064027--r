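#' Construct and validate a cohort table
#'
#' A cohort table holds one row per participant (controls and patients with
#' left, right or bilateral posterior lesions), demographic covariates, and a
#' participant-by-(test, measure) score matrix with an explicit observedness
#' mask so that missing entries are first-class.
#'
#' @param participants Data frame with columns `participant_id`, `group`
#'   (one of control/left/right/bilateral, matched case-insensitively),
#'   `age`, `education`, `lesion_volume`, `time_since_stroke`. The two lesion
#'   covariates must be absent (`NA`) for controls.
#' @param schema Named list of [test_spec] objects.
#' @param values Numeric matrix, rows in `participants` order, columns named
#'   `<test_id>__<measure_id>` in schema order.
#' @param observed Logical matrix of the same shape; `FALSE` marks a missing
#'   cell. Defaults to `!is.na(values)`.
#'
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(participants, schema, values,
                         observed = !is.na(values)) {
  stopifnot(is.data.frame(participants), is.matrix(values),
            is.logical(observed))
  req <- c("participant_id", "group", "age", "education",
           "lesion_volume", "time_since_stroke")
  miss <- setdiff(req, names(participants))
  if (length(miss))
    stop("participants is missing column(s): ", paste(miss, collapse = ", "))
  participants$participant_id <- as.character(participants$participant_id)
  dup <- participants$participant_id[duplicated(participants$participant_id)]
  if (length(dup))
    stop("duplicate participant_id: ", paste(unique(dup), collapse = ", "))
  participants$group <- normalize_group(participants$group)

  cols <- schema_columns(schema)
  if (!identical(colnames(values), cols)) {
    extra <- setdiff(colnames(values), cols)
    absent <- setdiff(cols, colnames(values))
    if (length(extra))
      stop("score columns not named in the schema: ",
           paste(extra, collapse = ", "))
    if (length(absent))
      stop("score columns required by the schema are absent: ",
           paste(absent, collapse = ", "))
    values <- values[, cols, drop = FALSE]
    observed <- observed[, cols, drop = FALSE]
  }
  if (!identical(dim(observed), dim(values)))
    stop("observed mask dimensions do not match values")
  if (nrow(values) != nrow(participants))
    stop("values has ", nrow(values), " rows but participants has ",
         nrow(participants))
  rownames(values) <- rownames(observed) <- participants$participant_id
  bad <- which(observed & !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite observed value at row '%s', column '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  values[!observed] <- NA_real_

  if (any(is.na(participants$age)) || any(participants$age <= 0))
    stop("age must be present and > 0 for every participant")
  ctrl <- participants$group == "control"
  if (any(ctrl & (!is.na(participants$lesion_volume) |
                  !is.na(participants$time_since_stroke))))
    stop("controls must not carry lesion_volume or time_since_stroke")

  structure(list(participants = participants, schema = schema,
                 values = values, observed = observed),
            class = "cohort_table")
}

normalize_group <- function(group) {
  g <- tolower(trimws(as.character(group)))
  ok <- c("control", "left", "right", "bilateral")
  bad <- setdiff(unique(g), ok)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  factor(g, levels = ok)
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<cohort_table> %d participants (%s), %d tests, %d score columns\n",
              nrow(x$participants),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(x$schema), ncol(x$values)))
  cat(sprintf("  missing: %.1f%% of cells\n", 100 * mean(!x$observed)))
  invisible(x)
}

#' Number of patients / controls in a cohort
#' @param cohort A [cohort_table].
#' @return Integer count.
#' @export
n_patients <- function(cohort) sum(cohort$participants$group != "control")

#' @rdname n_patients
#' @export
n_controls <- function(cohort) sum(cohort$participants$group == "control")

# stop unless the cohort can support a case-control analysis
assert_analysable <- function(cohort) {
  if (n_controls(cohort) < 2L)
    stop("analysis requires at least 2 controls")
  if (n_patients(cohort) < 1L)
    stop("analysis requires at least 1 patient")
  invisible(cohort)
}

#' Read a cohort from a wide-format CSV file
#'
#' One row per participant; demographic columns as in [cohort_table];
#' score columns named `<test_id>__<measure_id>`; an empty cell encodes a
#' missing score. Score columns not declared in the schema are rejected,
#' as are non-numeric score cells (reported with their row and column).
#'
#' @param path CSV file path.
#' @param schema Named list of [test_spec] objects (default [vot_battery()]).
#' @return A validated [cohort_table].
#' @export
read_cohort <- function(path, schema = vot_battery()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  demo <- c("participant_id", "group", "age", "education",
            "lesion_volume", "time_since_stroke")
  miss <- setdiff(demo, names(df))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  score_cols <- setdiff(names(df), demo)
  cols <- schema_columns(schema)
  extra <- setdiff(score_cols, cols)
  if (length(extra))
    stop("score columns not named in the schema: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(cols, score_cols)
  if (length(absent))
    stop("score columns required by the schema are absent: ",
         paste(absent, collapse = ", "))

  parse_num <- function(v, col, allow_empty = TRUE) {
    v <- trimws(v)
    empty <- !nzchar(v) | is.na(v)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!empty & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   v[bad[1]], bad[1], col))
    out
  }
  values <- vapply(cols, function(cl) parse_num(df[[cl]], cl),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, cols))
  participants <- data.frame(
    participant_id = df$participant_id,
    group = df$group,
    age = parse_num(df$age, "age"),
    education = parse_num(df$education, "education"),
    lesion_volume = parse_num(df$lesion_volume, "lesion_volume"),
    time_since_stroke = parse_num(df$time_since_stroke, "time_since_stroke"),
    stringsAsFactors = FALSE)
  cohort_table(participants, schema, values)
}

#' Write a cohort to a wide-format CSV file
#'
#' Inverse of [read_cohort()]: missing cells are written as empty strings and
#' round-trip to `FALSE` entries of the observedness mask.
#'
#' @param cohort A [cohort_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  vals <- cohort$values
  vals[!cohort$observed] <- NA_real_
  df <- cbind(cohort$participants,
              as.data.frame(vals, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarise missingness of a cohort
#'
#' @param cohort A [cohort_table].
#' @return Data frame with one row per test plus an `overall` row, giving the
#'   number of cells, missing count and missing fraction. Per-test counts
#'   partition the matrix, so the cell-weighted per-test fractions reproduce
#'   the overall fraction.
#' @export
summarize_missingness <- function(cohort) {
  test_of_col <- rep(vapply(cohort$schema, `[[`, "", "test_id"),
                     vapply(cohort$schema, function(ts) nrow(ts$measures), 0L))
  per <- lapply(unique(test_of_col), function(tid) {
    m <- cohort$observed[, test_of_col == tid, drop = FALSE]
    data.frame(test_id = tid, n_cells = length(m),
               n_missing = sum(!m), missing_fraction = mean(!m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- rbind(out, data.frame(
    test_id = "overall", n_cells = length(cohort$observed),
    n_missing = sum(!cohort$observed),
    missing_fraction = mean(!cohort$observed), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a bundle of result tables with a manifest
#'
#' Writes each table of the bundle as a deterministically named CSV
#' (RFC 4180, UTF-8, `.` decimal separator) plus a `manifest.json` listing
#' every file with its MD5 content hash. Writing the same bundle twice
#' produces byte-identical files.
#'
#' @param bundle Named list of data frames.
#' @param path Output directory (created if needed).
#' @return The manifest, invisibly (list with one entry per file).
#' @export
write_results <- function(bundle, path) {
  stopifnot(is.list(bundle))
  if (length(bundle) && is.null(names(bundle)))
    stop("bundle tables must be named")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path)
  entries <- list()
  for (nm in sort(names(bundle))) {
    fn <- paste0(nm, ".csv")
    fp <- file.path(path, fn)
    utils::write.csv(bundle[[nm]], fp, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    entries[[length(entries) + 1L]] <-
      list(file = fn, rows = nrow(bundle[[nm]]),
           md5 = unname(tools::md5sum(fp)))
  }
  manifest <- list(files = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
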