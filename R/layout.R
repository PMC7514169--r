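#' @rdname SystemLayout-class
#' @param nodeIds character vector of node labels.
#' @param gridCoords optional integer matrix (row, col) with one row per
#'   node, or `NULL`.
#' @return `SystemLayout()` and `gridLayout()` return a
#'   [SystemLayout-class] object.
#' @export
SystemLayout <- function(nodeIds, gridCoords = NULL) {
  nodeIds <- as.character(nodeIds)
  if (!is.null(gridCoords)) {
    gridCoords <- as.matrix(gridCoords)
    storage.mode(gridCoords) <- "integer"
    colnames(gridCoords) <- c("row", "col")
    rownames(gridCoords) <- nodeIds
  }
  new("SystemLayout", nodeIds = nodeIds, gridCoords = gridCoords)
}

#' @rdname SystemLayout-class
#' @param nrow,ncol grid dimensions.
#' @param prefix prefix for the generated node labels (default "node");
#'   nodes are numbered row-major, so `gridLayout(3, 3)` yields
#'   node1..node9 reading left-to-right, top-to-bottom.
#' @export
gridLayout <- function(nrow, ncol, prefix = "node") {
  coords <- cbind(row = rep(seq_len(nrow), each = ncol),
                  col = rep(seq_len(ncol), times = nrow))
  SystemLayout(paste0(prefix, seq_len(nrow * ncol)), coords)
}

#' @rdname SystemLayout-class
#' @export
setMethod("nodeIds", "SystemLayout", function(object) object@nodeIds)

#' @rdname SystemLayout-class
#' @export
setMethod("gridCoords", "SystemLayout", function(object) object@gridCoords)

#' @rdname SystemLayout-class
#' @export
setMethod("nNodes", "SystemLayout", function(object) length(object@nodeIds))

setMethod("show", "SystemLayout", function(object) {
  cat("SystemLayout with", length(object@nodeIds), "nodes")
  if (!is.null(object@gridCoords))
    cat(" on a", max(object@gridCoords[, 1L]), "x",
        max(object@gridCoords[, 2L]), "grid")
  cat("\n  nodes:", paste(utils::head(object@nodeIds, 6L), collapse = ", "),
      if (length(object@nodeIds) > 6L) "..." else "", "\n")
})

#' Euclidean displacement classes of node pairs on a grid
#'
#' Groups the unordered node pairs of a grid layout by the Euclidean
#' distance between their grid positions. Pairs in the same class are
#' treated as equivalent under the grid's symmetry, which is how a
#' relation learned on a node subset is extended to the full system and
#' how symmetry tying shares parameters during learning.
#'
#' @param layout a [SystemLayout-class] with grid coordinates.
#' @param nodes optional character vector restricting to a node subset.
#' @return a data.frame with columns `i`, `j` (node ids, i before j in
#'   layout order), `dist` (Euclidean grid distance) and `class` (the
#'   distance rounded to 9 digits, as a factor key).
#' @examples
#' head(pairDistanceClasses(gridLayout(3, 3)))
#' @export
pairDistanceClasses <- function(layout, nodes = NULL) {
  gc <- gridCoords(layout)
  if (is.null(gc))
    stop("layout has no grid coordinates")
  ids <- nodeIds(layout)
  if (!is.null(nodes)) {
    if (!all(nodes %in% ids)) stop("unknown node in subset")
    ids <- ids[ids %in% nodes]
  }
  idx <- match(ids, nodeIds(layout))
  pr <- t(utils::combn(seq_along(ids), 2L))
  d <- sqrt(rowSums((gc[idx[pr[, 1L]], , drop = FALSE] -
                     gc[idx[pr[, 2L]], , drop = FALSE])^2))
  data.frame(i = ids[pr[, 1L]], j = ids[pr[, 2L]], dist = d,
             class = format(round(d, 9L), trim = TRUE),
             stringsAsFactors = FALSE)
}
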