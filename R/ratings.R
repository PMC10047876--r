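#' Rating matrix for one rating occasion
#'
#' The unit of all agreement statistics: a subjects x raters matrix of
#' categorical ratings, `NA` marking a missing rating. The category
#' list is fixed up front (default the four Schroth curve types) so that
#' chance agreement is computed over the declared categories even when a
#' rater never used one of them.
#'
#' @param ratings Character matrix (subjects in rows, raters in
#'   columns) or a data.frame coercible to one. `NA` or `""` marks a
#'   missing rating.
#' @param categories Character vector of allowed categories.
#' @param occasion Optional occasion identifier kept as metadata.
#'
#' @return A `rating_matrix`: a character matrix with attributes
#'   `categories` and `occasion`.
#' @export
rating_matrix <- function(ratings, categories = curve_types(),
                          occasion = NA) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "character"
  m[!is.na(m) & m == ""] <- NA_character_
  bad <- !is.na(m) & !(m %in% categories)
  if (any(bad)) {
    stop("ratings outside the declared categories: ",
         paste(unique(m[bad]), collapse = ", "),
         " (allowed: ", paste(categories, collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("r", seq_len(ncol(m)))
  structure(m, categories = categories, occasion = occasion,
            class = c("rating_matrix", "matrix", "array"))
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("Rating matrix: %d subjects x %d raters, %d categories",
              nrow(x), ncol(x), length(attr(x, "categories"))))
  if (!is.na(attr(x, "occasion"))) {
    cat(", occasion ", attr(x, "occasion"), sep = "")
  }
  cat("\n")
  print(unclass(x)[, , drop = FALSE], quote = FALSE)
  invisible(x)
}

# subjects x q matrix of r_ik counts (raters placing subject i in
# category k); NA ratings contribute nothing
category_counts <- function(rm) {
  cats <- attr(rm, "categories")
  counts <- vapply(cats, function(k) {
    rowSums(!is.na(rm) & rm == k)
  }, numeric(nrow(rm)))
  matrix(counts, nrow = nrow(rm), ncol = length(cats),
         dimnames = list(rownames(rm), cats))
}

#' Validate a long-format ratings CSV
#'
#' Checks a long-format ratings table (columns `subject_id`,
#' `rater_id`, `occasion`, `rating`) and either reports every violation
#' with its file row number, or returns the parsed table. Empty rating
#' cells are accepted as missing.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param categories Allowed rating categories.
#'
#' @return A list with elements `data` (the validated data.frame, or
#'   `NULL` when invalid) and `errors` (character vector, empty when
#'   valid). Row numbers in messages count the header as row 1.
#' @export
validate_ratings <- function(path, categories = curve_types()) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  errors <- character()
  needed <- c("subject_id", "rater_id", "occasion", "rating")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    return(list(data = NULL,
                errors = paste("missing columns:",
                               paste(missing_cols, collapse = ", "))))
  }
  rowno <- seq_len(nrow(df)) + 1L  # header is file row 1

  df$rating <- trimws(as.character(df$rating))
  df$rating[df$rating == ""] <- NA_character_
  bad_cat <- !is.na(df$rating) & !(df$rating %in% categories)
  if (any(bad_cat)) {
    errors <- c(errors, sprintf(
      "row %d: rating '%s' not in {%s}", rowno[bad_cat],
      df$rating[bad_cat], paste(categories, collapse = ", ")))
  }

  occ <- suppressWarnings(as.integer(df$occasion))
  bad_occ <- is.na(occ)
  if (any(bad_occ)) {
    errors <- c(errors, sprintf(
      "row %d: occasion '%s' is not an integer", rowno[bad_occ],
      as.character(df$occasion)[bad_occ]))
  } else {
    df$occasion <- occ
  }

  key <- paste(df$subject_id, df$rater_id, df$occasion, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    errors <- c(errors, sprintf(
      "row %d: duplicate (subject '%s', rater '%s', occasion %s)",
      rowno[dup], df$subject_id[dup], df$rater_id[dup],
      as.character(df$occasion)[dup]))
  }

  if (length(errors)) list(data = NULL, errors = errors)
  else list(data = df, errors = character())
}

#' Read long-format ratings into per-occasion rating matrices
#'
#' @param path CSV path or data.frame with columns `subject_id`,
#'   `rater_id`, `occasion`, `rating`.
#' @param categories Allowed rating categories.
#'
#' @return A named list of [rating_matrix()] objects, one per occasion
#'   (names `"1"`, `"2"`, ...). All occasions share the same subject
#'   rows and rater columns; pairs absent from the file are `NA`.
#' @export
read_ratings <- function(path, categories = curve_types()) {
  v <- validate_ratings(path, categories)
  if (length(v$errors)) {
    stop("invalid ratings file:\n  ",
         paste(v$errors, collapse = "\n  "), call. = FALSE)
  }
  df <- v$data
  subjects <- unique(df$subject_id)
  raters <- unique(df$rater_id)
  occasions <- sort(unique(df$occasion))
  out <- lapply(occasions, function(o) {
    m <- matrix(NA_character_, nrow = length(subjects),
                ncol = length(raters),
                dimnames = list(subjects, raters))
    sub <- df[df$occasion == o, , drop = FALSE]
    m[cbind(match(sub$subject_id, subjects),
            match(sub$rater_id, raters))] <- sub$rating
    rating_matrix(m, categories = categories, occasion = o)
  })
  names(out) <- as.character(occasions)
  out
}

#' Write per-occasion rating matrices as a long-format CSV
#'
#' Inverse of [read_ratings()]: every (subject, rater, occasion) cell is
#' written, missing ratings as empty cells, so a write/read round trip
#' preserves the matrices exactly.
#'
#' @param matrices Named list of [rating_matrix()] objects (names are
#'   the occasion ids) or a single `rating_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(matrices, path) {
  if (inherits(matrices, "rating_matrix")) {
    occ <- attr(matrices, "occasion")
    matrices <- stats::setNames(list(matrices),
                                if (is.na(occ)) "1" else as.character(occ))
  }
  rows <- do.call(rbind, lapply(names(matrices), function(o) {
    m <- matrices[[o]]
    data.frame(
      subject_id = rep(rownames(m), times = ncol(m)),
      rater_id = rep(colnames(m), each = nrow(m)),
      occasion = o,
      rating = ifelse(is.na(as.vector(m)), "", as.vector(m)),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
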