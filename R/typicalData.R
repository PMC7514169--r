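#' @rdname TypicalData-class
#' @param states matrix of observations, one row per observation and one
#'   column per node: either 1-based integer state indices or repertoire
#'   labels (converted via `repertoire`).
#' @param layout a [SystemLayout-class]; built from the column names (or
#'   generated node ids) when omitted.
#' @param repertoire character vector of the m state labels in index
#'   order.
#' @return a [TypicalData-class].
#' @export
TypicalData <- function(states, repertoire, layout = NULL) {
  states <- as.matrix(states)
  repertoire <- as.character(repertoire)
  if (is.character(states) ||
      (is.numeric(states) && !all(states == round(states)))) {
    idx <- match(as.character(states), repertoire)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      rc <- arrayInd(bad, dim(states))
      stop("state label '", as.character(states)[bad],
           "' at row ", rc[1L], ", column ", rc[2L],
           " is not in the repertoire")
    }
    states <- matrix(idx, nrow = nrow(states), ncol = ncol(states),
                     dimnames = dimnames(states))
  }
  storage.mode(states) <- "integer"
  if (is.null(layout)) {
    ids <- colnames(states)
    if (is.null(ids)) ids <- paste0("node", seq_len(ncol(states)))
    layout <- SystemLayout(ids)
  }
  colnames(states) <- nodeIds(layout)
  new("TypicalData", states = states, layout = layout,
      repertoire = repertoire)
}

#' @rdname TypicalData-class
#' @export
setMethod("stateMatrix", "TypicalData", function(object) object@states)

#' @rdname TypicalData-class
#' @export
setMethod("repertoire", "TypicalData", function(object) object@repertoire)

#' @rdname TypicalData-class
#' @export
setMethod("systemLayout", "TypicalData", function(object) object@layout)

#' @rdname TypicalData-class
#' @export
setMethod("nObservations", "TypicalData", function(object) nrow(object@states))

setMethod("show", "TypicalData", function(object) {
  cat("TypicalData:", nrow(object@states), "observations of",
      ncol(object@states), "nodes,", length(object@repertoire),
      "repertoire states\n")
  cat("  repertoire:", paste(object@repertoire, collapse = ", "), "\n")
})

#' Restrict typical data to a node subset
#'
#' @param T a [TypicalData-class].
#' @param nodes character vector of node ids to keep (layout order is
#'   preserved).
#' @return a [TypicalData-class] over the subset, with grid coordinates
#'   carried over when present.
#' @export
subsetNodes <- function(T, nodes) {
  ids <- nodeIds(systemLayout(T))
  if (!all(nodes %in% ids)) stop("unknown node in subset")
  keep <- ids[ids %in% nodes]
  gc <- gridCoords(systemLayout(T))
  lay <- SystemLayout(keep, if (is.null(gc)) NULL else gc[keep, , drop = FALSE])
  TypicalData(stateMatrix(T)[, keep, drop = FALSE], repertoire(T), lay)
}

#' Empirical state distribution of typical data
#'
#' Tabulates the observations onto the canonical state enumeration,
#' yielding the empirical probability vector used by the exact
#' expected-float-entropy and conditional-entropy computations.
#'
#' @param T a [TypicalData-class].
#' @param space optional [StateSpace-class] (constructed from T when
#'   omitted).
#' @return the [StateSpace-class] with its `prob` slot filled.
#' @export
empiricalDistribution <- function(T, space = NULL) {
  if (is.null(space))
    space <- StateSpace(ncol(stateMatrix(T)), length(repertoire(T)))
  idx <- encodeState(space, stateMatrix(T))
  p <- numeric(space@size)
  tab <- table(idx)
  p[as.numeric(names(tab))] <- as.numeric(tab) / length(idx)
  stateProb(space) <- p
  space
}

#' Read and write typical data tables
#'
#' Typical data is serialised as a TSV of repertoire labels (one row per
#' observation, header = node ids) plus a JSON sidecar at
#' `<path>.json` holding the repertoire order and any grid coordinates.
#'
#' @param path path of the TSV file.
#' @return `readTypicalData` returns a [TypicalData-class];
#'   `writeTypicalData` invisibly returns `path`.
#' @export
readTypicalData <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar ", side, " (repertoire definition)")
  meta <- jsonlite::fromJSON(side)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) < 1L) stop("typical data file ", path, " is empty")
  gc <- meta$grid_coords
  lay <- SystemLayout(colnames(df),
                      if (is.null(gc)) NULL else as.matrix(gc))
  TypicalData(as.matrix(df), as.character(meta$repertoire), lay)
}

#' @rdname readTypicalData
#' @param T a [TypicalData-class].
#' @param provenance optional list recorded in the sidecar.
#' @export
writeTypicalData <- function(T, path, provenance = NULL) {
  lab <- matrix(repertoire(T)[stateMatrix(T)], nrow = nObservations(T),
                dimnames = dimnames(stateMatrix(T)))
  utils::write.table(as.data.frame(lab, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gc <- gridCoords(systemLayout(T))
  meta <- list(repertoire = repertoire(T),
               layout = nodeIds(systemLayout(T)))
  if (!is.null(gc)) meta$grid_coords <- unname(apply(gc, 2L, as.integer))
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}
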