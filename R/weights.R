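#' Partial-credit agreement weight matrix
#'
#' A weight matrix assigns partial credit `w[k, l]` in `[0, 1]` to a
#' pair of categories `(k, l)`: 1 on the diagonal (full agreement), 0
#' for pairs that deserve no credit, intermediate values for clinically
#' similar categories. The matrix must be symmetric.
#'
#' @param w Numeric q x q matrix.
#' @param categories Character vector of category labels; defaults to
#'   existing dimnames of `w`.
#'
#' @return A `weight_matrix` (a numeric matrix with class attribute and
#'   category dimnames).
#' @export
weight_matrix <- function(w, categories = rownames(w)) {
  w <- as.matrix(w)
  q <- nrow(w)
  if (q < 2L || ncol(w) != q) {
    stop("weights must be a square matrix with q >= 2", call. = FALSE)
  }
  if (is.null(categories) || length(categories) != q) {
    stop("need one category label per row", call. = FALSE)
  }
  storage.mode(w) <- "double"
  if (anyNA(w) || any(w < 0) || any(w > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(diag(w) - 1) > 1e-12)) {
    stop("weight matrix diagonal must be all 1", call. = FALSE)
  }
  if (any(abs(w - t(w)) > 1e-12)) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  dimnames(w) <- list(categories, categories)
  class(w) <- c("weight_matrix", class(w))
  w
}

#' Default Schroth partial-agreement weights
#'
#' The clinical partial-agreement weights over the four Schroth curve
#' types. Full credit (1.00) on the diagonal; 0.75 between patterns
#' differing only in pelvis balance (3c vs 3cp, 4c vs 4cp), where the
#' exercise prescription differs only in the pelvis-related exercises;
#' 0.50 between the two balanced-pelvis patterns (3c vs 4c); 0.00 for
#' pairings whose treatments act in opposite directions or on different
#' regions.
#'
#' @return A 4 x 4 [weight_matrix()] over [curve_types()].
#' @export
#' @examples
#' schroth_weights()["3c", "3cp"]
schroth_weights <- function() {
  cats <- curve_types()
  w <- matrix(c(
    1.00, 0.75, 0.50, 0.00,
    0.75, 1.00, 0.00, 0.00,
    0.50, 0.00, 1.00, 0.75,
    0.00, 0.00, 0.75, 1.00
  ), nrow = 4, byrow = TRUE, dimnames = list(cats, cats))
  weight_matrix(w)
}

#' Identity weights (unweighted agreement)
#'
#' The identity weight matrix gives credit only for exact category
#' matches; agreement coefficients computed with it reduce to their
#' unweighted forms.
#'
#' @param q Number of categories (>= 2), or a character vector of
#'   category labels.
#' @return A q x q [weight_matrix()].
#' @export
identity_weights <- function(q = curve_types()) {
  if (is.character(q)) {
    cats <- q
  } else {
    if (q < 2) stop("q must be >= 2", call. = FALSE)
    cats <- as.character(seq_len(q))
  }
  weight_matrix(diag(length(cats)), categories = cats)
}

#' Read a weight matrix from CSV
#'
#' Expects a header row of category labels and a leading label column,
#' i.e. the layout written by [write_weights()].
#'
#' @param path CSV file path.
#' @return A [weight_matrix()].
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  w <- as.matrix(df)
  if (!identical(rownames(w), colnames(w))) {
    stop("weight CSV row and column labels differ", call. = FALSE)
  }
  weight_matrix(w)
}

#' Write a weight matrix to CSV
#'
#' @param w A [weight_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  utils::write.csv(as.data.frame(unclass(w)), path, row.names = TRUE)
  invisible(path)
}
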