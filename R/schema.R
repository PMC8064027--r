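#' Define a neuropsychological test
#'
#' A test specification records the test identifier, the cognitive domain it
#' probes, its dependent measures with their score direction, and whether the
#' test enters the domain composite scores.
#'
#' @param test_id Character scalar, unique test identifier.
#' @param domain One of `"word"`, `"object"`, `"face"`, `"low_level"`,
#'   `"mixed"`.
#' @param measures Data frame with columns `measure_id` and `direction`
#'   (`"higher_is_better"` or `"lower_is_better"`), one row per dependent
#'   measure. A character vector of measure ids is accepted and assumed
#'   `higher_is_better`.
#' @param in_composite Logical; whether the test contributes to its domain's
#'   composite score. Only permitted for the word, object and face domains.
#'
#' @return An object of class `test_spec`.
#' @export
test_spec <- function(test_id, domain, measures = "accuracy",
                      in_composite = FALSE) {
  stopifnot(is.character(test_id), length(test_id) == 1L, nzchar(test_id))
  domain <- match.arg(domain, c("word", "object", "face", "low_level", "mixed"))
  if (is.character(measures)) {
    measures <- data.frame(measure_id = measures,
                           direction = "higher_is_better",
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(measures),
            all(c("measure_id", "direction") %in% names(measures)))
  if (nrow(measures) < 1L)
    stop("test '", test_id, "': at least one measure is required")
  bad <- setdiff(measures$direction, c("higher_is_better", "lower_is_better"))
  if (length(bad))
    stop("test '", test_id, "': unknown direction ", paste(bad, collapse = ", "))
  if (anyDuplicated(measures$measure_id))
    stop("test '", test_id, "': duplicate measure ids")
  if (in_composite && !domain %in% c("word", "object", "face"))
    stop("test '", test_id, "': in_composite requires domain word/object/face")
  structure(list(test_id = test_id, domain = domain,
                 measures = measures[, c("measure_id", "direction")],
                 in_composite = isTRUE(in_composite)),
            class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf("<test_spec> %s [%s]%s: %s\n", x$test_id, x$domain,
              if (x$in_composite) " (composite)" else "",
              paste(x$measures$measure_id, collapse = ", ")))
  invisible(x)
}

#' The default 22-test visual recognition battery
#'
#' Battery schema for a case-series assessment of word, object and face
#' recognition after posterior stroke: three low/intermediate-level visual
#' tests, eight word tests, six object tests and five face tests. Four tests
#' per higher-level domain (delayed matching, surprise recognition, the
#' domain decision test and the domain naming/reading test) are flagged for
#' the composite scores so that task demands are matched across domains.
#' Decision and reading/naming tests carry accuracy and response-time
#' measures; the remaining tests carry accuracy only.
#'
#' @return A list of [test_spec] objects of length 22.
#' @export
vot_battery <- function() {
  acc_rt <- data.frame(
    measure_id = c("accuracy", "rt"),
    direction = c("higher_is_better", "lower_is_better"),
    stringsAsFactors = FALSE)
  specs <- list(
    # low / intermediate level vision
    test_spec("rvf_deficit",          "low_level"),
    test_spec("visual_acuity",        "low_level"),
    test_spec("lpost",                "low_level"),
    # words
    test_spec("delayed_match_words",  "word", in_composite = TRUE),
    test_spec("surprise_recog_words", "word", in_composite = TRUE),
    test_spec("lexical_decision",     "word", acc_rt, in_composite = TRUE),
    test_spec("word_reading",         "word", acc_rt, in_composite = TRUE),
    test_spec("regular_word_reading", "word"),
    test_spec("exception_word_reading", "word"),
    test_spec("nonword_reading",      "word"),
    test_spec("text_reading",         "word"),
    # objects
    test_spec("delayed_match_objects",  "object", in_composite = TRUE),
    test_spec("surprise_recog_objects", "object", in_composite = TRUE),
    test_spec("object_decision",        "object", acc_rt, in_composite = TRUE),
    test_spec("picture_naming",         "object", acc_rt, in_composite = TRUE),
    test_spec("chmt",                   "object"),
    test_spec("object_categorisation",  "object"),
    # faces
    test_spec("delayed_match_faces",  "face", in_composite = TRUE),
    test_spec("surprise_recog_faces", "face", in_composite = TRUE),
    test_spec("face_familiarity",     "face", acc_rt, in_composite = TRUE),
    test_spec("famous_face_naming",   "face", in_composite = TRUE),
    test_spec("cfmt",                 "face")
  )
  names(specs) <- vapply(specs, `[[`, "", "test_id")
  specs
}

#' Read or write a battery schema file
#'
#' The schema file is JSON: an array of objects with fields `test_id`,
#' `domain`, `in_composite` and `measures` (array of
#' `{measure_id, direction}`). A copy of the default battery ships with the
#' package under `extdata/vot_battery.json`.
#'
#' @param path File path.
#' @return `read_test_schema()` returns a named list of [test_spec] objects;
#'   `write_test_schema()` returns `path` invisibly.
#' @export
read_test_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  specs <- lapply(raw, function(el) {
    meas <- do.call(rbind, lapply(el$measures, function(m)
      data.frame(measure_id = m$measure_id, direction = m$direction,
                 stringsAsFactors = FALSE)))
    test_spec(el$test_id, el$domain, meas, isTRUE(el$in_composite))
  })
  names(specs) <- vapply(specs, `[[`, "", "test_id")
  specs
}

#' @rdname read_test_schema
#' @param schema List of [test_spec] objects.
#' @export
write_test_schema <- function(schema, path) {
  out <- lapply(schema, function(ts) {
    list(test_id = ts$test_id, domain = ts$domain,
         in_composite = ts$in_composite,
         measures = lapply(seq_len(nrow(ts$measures)), function(i)
           list(measure_id = ts$measures$measure_id[i],
                direction = ts$measures$direction[i])))
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# column names of the score block implied by a schema, in schema order
schema_columns <- function(schema) {
  unlist(lapply(schema, function(ts)
    paste(ts$test_id, ts$measures$measure_id, sep = "__")), use.names = FALSE)
}
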