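#' @rdname WeightedRelation-class
#' @param labels character vector of index labels (nodes or repertoire
#'   states).
#' @param values square numeric matrix of strengths in \[0, 1\] with
#'   unit diagonal.
#' @param symmetric logical; enforce symmetry (default TRUE).
#' @return a [WeightedRelation-class].
#' @export
WeightedRelation <- function(labels, values, symmetric = TRUE) {
  values <- as.matrix(values)
  dimnames(values) <- list(labels, labels)
  new("WeightedRelation", labels = as.character(labels), values = values,
      symmetric = isTRUE(symmetric))
}

#' @rdname WeightedRelation-class
#' @param fill off-diagonal value for `constantRelation` (default 1).
#' @export
constantRelation <- function(labels, fill = 1) {
  d <- length(labels)
  v <- matrix(fill, d, d)
  diag(v) <- 1
  WeightedRelation(labels, v)
}

#' Draw a uniformly random reflexive symmetric weighted relation
#'
#' Each off-diagonal upper-triangular entry is drawn i.i.d. uniform on
#' \[0, 1\] and mirrored below the diagonal; the diagonal is 1. This is
#' the null model from which Monte-Carlo efe-histograms are built.
#'
#' @param labels character vector of index labels.
#' @return a [WeightedRelation-class].
#' @seealso [efeHistogram()]
#' @export
randomRelation <- function(labels) {
  d <- length(labels)
  v <- matrix(0, d, d)
  up <- upper.tri(v)
  v[up] <- stats::runif(sum(up))
  v <- v + t(v)
  diag(v) <- 1
  WeightedRelation(labels, v)
}

#' @rdname WeightedRelation-class
#' @export
setMethod("relationMatrix", "WeightedRelation", function(object) object@values)

#' @rdname WeightedRelation-class
#' @export
setMethod("relationLabels", "WeightedRelation", function(object) object@labels)

setMethod("show", "WeightedRelation", function(object) {
  d <- length(object@labels)
  cat("WeightedRelation on", d, "labels",
      if (object@symmetric) "(reflexive, symmetric)\n" else "(reflexive)\n")
  print(round(object@values[seq_len(min(d, 6L)), seq_len(min(d, 6L))], 5L))
  if (d > 6L) cat("  ... (", d, "x", d, " matrix)\n", sep = "")
})

#' Relation induced on the nodes by a data element
#'
#' Given a relation U on the repertoire and a complete observation, the
#' induced relation on the nodes reads U at the pair of states the
#' observation assigns to each node pair: entry (a, b) is
#' U(state of a, state of b). It inherits reflexivity and symmetry
#' from U.
#'
#' @param U a [WeightedRelation-class] over the repertoire.
#' @param element integer vector of 1-based state indices, one per node
#'   (in layout order).
#' @param nodeLabels optional node ids for the result's labels.
#' @return a [WeightedRelation-class] over the nodes.
#' @export
inducedRelation <- function(U, element, nodeLabels = NULL) {
  uv <- relationMatrix(U)
  m <- nrow(uv)
  element <- as.integer(element)
  if (any(element < 1L) || any(element > m))
    stop("invalid element: state index outside the repertoire range 1..", m)
  if (is.null(nodeLabels)) nodeLabels <- paste0("node", seq_along(element))
  WeightedRelation(nodeLabels, uv[element, element, drop = FALSE],
                   symmetric = U@symmetric)
}

#' Distance between two weighted relations
#'
#' The order-n distance sums |R - R'|^n over all ordered index pairs
#' (diagonal included) and takes the n-th root; order `Inf` gives the
#' maximum absolute difference. For reflexive symmetric relations the
#' order-1 distance equals twice the sum over strict upper-triangular
#' pairs.
#'
#' @param R,R2 [WeightedRelation-class] objects on the same index set.
#' @param order a positive number or `Inf` (default 1).
#' @param upperOnly logical; restrict the sum to strict upper-triangular
#'   pairs (ordering-equivalent to the full sum for symmetric inputs,
#'   at half the magnitude). Default FALSE.
#' @return a nonnegative number.
#' @export
relationDistance <- function(R, R2, order = 1, upperOnly = FALSE) {
  if (!identical(relationLabels(R), relationLabels(R2)))
    stop("incompatible relations: index sets differ")
  dif <- abs(relationMatrix(R) - relationMatrix(R2))
  if (upperOnly) dif <- dif[upper.tri(dif)]
  if (is.infinite(order)) return(max(dif))
  if (order <= 0) stop("order must be positive")
  sum(dif^order)^(1 / order)
}

#' Read and write weighted relation tables
#'
#' Relations are stored as CSV matrices whose first column and header
#' row carry the index labels, or as JSON objects
#' `{"labels": [...], "matrix": [[...], ...]}`. Reflexivity and
#' symmetry are validated on read.
#'
#' @param path file path; format chosen by extension (".json" for JSON,
#'   CSV otherwise).
#' @param symmetric logical; require symmetry on read (default TRUE).
#' @return `readRelation` returns a [WeightedRelation-class];
#'   `writeRelation` invisibly returns `path`.
#' @export
readRelation <- function(path, symmetric = TRUE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    v <- as.matrix(obj$matrix)
    labs <- as.character(obj$labels)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1L,
                          colClasses = "character")
    v <- apply(as.matrix(df), c(1L, 2L), as.numeric)
    labs <- rownames(df)
    if (nrow(v) != ncol(v))
      stop("relation table in ", path, " is not square")
    if (!identical(labs, colnames(df)))
      stop("relation table row and column labels differ")
  }
  WeightedRelation(labs, v, symmetric = symmetric)
}

#' @rdname readRelation
#' @param R a [WeightedRelation-class].
#' @param digits decimal digits written (default 6, enough to round-trip
#'   the dyadic grid values the optimiser produces).
#' @export
writeRelation <- function(R, path, digits = 6L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(labels = relationLabels(R),
                              matrix = unname(relationMatrix(R))),
                         path, digits = NA, auto_unbox = FALSE)
  } else {
    v <- round(relationMatrix(R), digits)
    df <- as.data.frame(v, check.names = FALSE)
    utils::write.csv(df, path, row.names = TRUE)
  }
  invisible(path)
}
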