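#' Construct a feature table
#'
#' A feature table is a samples x features numeric matrix of non-negative
#' abundances, either raw counts (`mode = "counts"`) or per-sample relative
#' abundances (`mode = "relative"`, every row summing to 1). It is the unit
#' all analyses in the package consume. Row names are sample identifiers,
#' column names feature identifiers; both must be unique.
#'
#' @param values numeric matrix (or object coercible to one), samples in rows.
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `feature_table`: a list with elements `values`
#'   (the matrix) and `mode`.
#' @examples
#' ft <- feature_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))))
#' ft
#' @export
feature_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  }
  x <- structure(list(values = values, mode = mode), class = "feature_table")
  validate_feature_table(x)
  x
}

#' Validate feature table invariants
#'
#' Checks non-negativity, absence of missing values, uniqueness of sample and
#' feature identifiers, and (in relative mode) unit row sums within 1e-9.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  if (anyNA(v)) {
    stop("feature table contains missing values")
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative abundance at sample '%s', feature '%s'",
      rownames(v)[bad[1]], colnames(v)[bad[2]]
    ))
  }
  if (anyDuplicated(rownames(v))) {
    stop(sprintf(
      "duplicated sample identifier: '%s'",
      rownames(v)[anyDuplicated(rownames(v))]
    ))
  }
  if (anyDuplicated(colnames(v))) {
    stop(sprintf(
      "duplicated feature identifier: '%s'",
      colnames(v)[anyDuplicated(colnames(v))]
    ))
  }
  if (x$mode == "relative") {
    rs <- rowSums(v)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off)) {
      stop(sprintf(
        "relative-mode rows must sum to 1; sample '%s' sums to %g",
        rownames(v)[off[1]], rs[off[1]]
      ))
    }
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features, mode = %s\n",
    nrow(x$values), ncol(x$values), x$mode
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Sample and feature identifiers of a feature table
#' @param x a `feature_table`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(as.matrix(x))

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(as.matrix(x))

#' Convert a counts table to relative abundances
#'
#' Divides each sample row by its total. Rows summing to zero are not
#' normalizable and raise an error naming the offending sample.
#'
#' @param x a counts-mode `feature_table`.
#' @return A relative-mode `feature_table` of identical shape.
#' @examples
#' ft <- feature_table(rbind(a = c(2, 2), b = c(10, 0)))
#' as.matrix(to_relative(ft))
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$mode == "relative") {
    return(x)
  }
  v <- x$values
  rs <- rowSums(v)
  if (any(rs == 0)) {
    stop(sprintf(
      "cannot normalize all-zero sample '%s'",
      rownames(v)[which(rs == 0)[1]]
    ))
  }
  feature_table(v / rs, mode = "relative")
}

# internal: coerce feature_table or bare matrix to a numeric matrix
ft_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}
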