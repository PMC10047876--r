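#' Schroth curve-type categories
#'
#' The four Schroth curve patterns: `3c` and `3cp` are thoracic-major
#' patterns, `4c` and `4cp` thoracolumbar/lumbar-major; the "p" suffix
#' marks an imbalanced (displaced) pelvis.
#'
#' @return Character vector of the four category labels, in canonical
#'   order `c("3c", "3cp", "4c", "4cp")`.
#' @export
#' @examples
#' curve_types()
curve_types <- function() {
  c("3c", "3cp", "4c", "4cp")
}

#' Postural observation record
#'
#' Bundles the four boolean postural features the classification
#' algorithm consumes. All four fields are always recorded even when a
#' branch of the decision tree does not consult them.
#'
#' @param pelvis_balanced Logical; `TRUE` when the pelvis is not
#'   displaced relative to the midline.
#' @param pelvis_lumbar_coupled Logical; `TRUE` when the lumbar block
#'   and the pelvis block deviate in the same direction ("coupled").
#' @param prominent_hip Logical; `TRUE` when a prominent hip is
#'   observed.
#' @param thoracic_dominant Logical; `TRUE` when the thoracic
#'   prominence (rib hump) is judged more significant than the lumbar
#'   prominence. Callers must set this `FALSE` on a tie.
#'
#' @return An object of class `postural_observation`.
#' @export
#' @examples
#' postural_observation(FALSE, TRUE, FALSE, TRUE)
postural_observation <- function(pelvis_balanced, pelvis_lumbar_coupled,
                                 prominent_hip, thoracic_dominant) {
  fields <- list(
    pelvis_balanced = pelvis_balanced,
    pelvis_lumbar_coupled = pelvis_lumbar_coupled,
    prominent_hip = prominent_hip,
    thoracic_dominant = thoracic_dominant
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop("'", nm, "' must be a single non-missing logical value",
           call. = FALSE)
    }
  }
  structure(fields, class = "postural_observation")
}

#' @export
print.postural_observation <- function(x, ...) {
  cat("Postural observation:\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Classify a Schroth curve type from postural features
#'
#' Deterministic rule engine for the Schroth curve-type classification
#' algorithm. The tree first evaluates pelvis displacement relative to
#' midline. An unbalanced pelvis leads to the pelvis-lumbar coupling
#' check: coupled blocks give `3cp`, uncoupled give `4cp`. With a
#' balanced pelvis the deciding step is the comparison of thoracic and
#' lumbar prominences: thoracic dominant gives `3c`, otherwise `4c`.
#' For a balanced pelvis the coupling and prominent-hip findings are
#' recorded in the trace as confirmatory observations but do not change
#' the outcome, so the function is total over all 16 feature
#' combinations.
#'
#' @param obs A [postural_observation()].
#'
#' @return A list of class `curve_classification` with elements
#'   `curve_type` (one of [curve_types()]) and `trace`, a data.frame of
#'   `(step, answer)` rows replaying every branch taken.
#' @export
#' @examples
#' classify_curve_type(postural_observation(FALSE, TRUE, FALSE, TRUE))$curve_type
classify_curve_type <- function(obs) {
  if (!inherits(obs, "postural_observation")) {
    obs <- do.call(postural_observation, as.list(obs))
  }
  steps <- character()
  answers <- logical()
  note <- function(step, answer) {
    steps <<- c(steps, step)
    answers <<- c(answers, answer)
  }

  note("pelvis_balanced", obs$pelvis_balanced)
  if (!obs$pelvis_balanced) {
    note("pelvis_lumbar_coupled", obs$pelvis_lumbar_coupled)
    type <- if (obs$pelvis_lumbar_coupled) "3cp" else "4cp"
  } else {
    # confirmatory checks; the prominence comparison decides
    note("pelvis_lumbar_uncoupled", !obs$pelvis_lumbar_coupled)
    note("prominent_hip", obs$prominent_hip)
    note("thoracic_dominant", obs$thoracic_dominant)
    type <- if (obs$thoracic_dominant) "3c" else "4c"
  }

  structure(
    list(
      curve_type = type,
      trace = data.frame(step = steps, answer = answers,
                         stringsAsFactors = FALSE)
    ),
    class = "curve_classification"
  )
}

#' @export
print.curve_classification <- function(x, ...) {
  cat("Schroth curve type:", x$curve_type, "\n")
  cat("Decision trace:\n")
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("  %-24s %s\n", x$trace$step[i],
                if (x$trace$answer[i]) "yes" else "no"))
  }
  invisible(x)
}

#' Full truth table of the classification algorithm
#'
#' Enumerates all 16 combinations of the four boolean postural features
#' together with the curve type each one classifies to.
#'
#' @return A data.frame with one row per combination: the four feature
#'   columns plus `curve_type`.
#' @export
#' @examples
#' table(curve_truth_table()$curve_type)
curve_truth_table <- function() {
  grid <- expand.grid(
    pelvis_balanced = c(FALSE, TRUE),
    pelvis_lumbar_coupled = c(FALSE, TRUE),
    prominent_hip = c(FALSE, TRUE),
    thoracic_dominant = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE
  )
  grid$curve_type <- vapply(seq_len(nrow(grid)), function(i) {
    classify_curve_type(postural_observation(
      grid$pelvis_balanced[i], grid$pelvis_lumbar_coupled[i],
      grid$prominent_hip[i], grid$thoracic_dominant[i]
    ))$curve_type
  }, character(1))
  grid
}

#' Batch-classify postural observations from a data.frame or CSV
#'
#' @param x A data.frame (or path to a CSV file) with columns
#'   `subject_id`, `pelvis_balanced`, `pelvis_lumbar_coupled`,
#'   `prominent_hip`, `thoracic_dominant`. Boolean columns may be
#'   logical or the strings "true"/"false".
#' @param output Optional path; when given, the result is also written
#'   as CSV.
#'
#' @return The input data.frame with two added columns: `curve_type`
#'   and `trace` (the branch decisions serialized as
#'   `step=yes/no` pairs separated by `;`).
#' @export
classify_table <- function(x, output = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  needed <- c("subject_id", "pelvis_balanced", "pelvis_lumbar_coupled",
              "prominent_hip", "thoracic_dominant")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  to_bool <- function(v, col) {
    if (is.logical(v)) return(v)
    out <- tolower(trimws(as.character(v)))
    bad <- !out %in% c("true", "false")
    if (any(bad)) {
      stop("column '", col, "' has non-boolean values at rows ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    out == "true"
  }
  for (col in needed[-1]) x[[col]] <- to_bool(x[[col]], col)

  res <- lapply(seq_len(nrow(x)), function(i) {
    classify_curve_type(postural_observation(
      x$pelvis_balanced[i], x$pelvis_lumbar_coupled[i],
      x$prominent_hip[i], x$thoracic_dominant[i]
    ))
  })
  x$curve_type <- vapply(res, `[[`, character(1), "curve_type")
  x$trace <- vapply(res, function(r) {
    paste(sprintf("%s=%s", r$trace$step,
                  ifelse(r$trace$answer, "yes", "no")), collapse = ";")
  }, character(1))
  if (!is.null(output)) {
    utils::write.csv(x, output, row.names = FALSE)
  }
  x
}
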