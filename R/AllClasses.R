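#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SystemLayout: the nodes of a multivariate system
#'
#' A `SystemLayout` names the nodes of the system under study and,
#' optionally, places them on an integer grid. Grid coordinates are used
#' for symmetry tying during relation learning and for constructing
#' derived tuple nodes; systems without spatial structure simply omit
#' them.
#'
#' @slot nodeIds character vector of unique node labels, in canonical
#'   order (row-major for grids).
#' @slot gridCoords either `NULL` or an integer matrix with one row per
#'   node (rownames = node ids) and columns `row`, `col`.
#'
#' @examples
#' gridLayout(3, 3)
#' SystemLayout(c("a", "b", "c"))
#' @exportClass SystemLayout
setClass("SystemLayout",
  representation(nodeIds = "character", gridCoords = "matrixOrNULL"))

setValidity("SystemLayout", function(object) {
  msg <- NULL
  if (length(object@nodeIds) < 1L)
    msg <- c(msg, "layout must contain at least one node")
  if (anyDuplicated(object@nodeIds))
    msg <- c(msg, "node ids must be unique")
  gc <- object@gridCoords
  if (!is.null(gc)) {
    if (ncol(gc) != 2L)
      msg <- c(msg, "gridCoords must have columns (row, col)")
    else {
      if (!identical(rownames(gc), object@nodeIds))
        msg <- c(msg, "gridCoords rownames must equal nodeIds in order")
      if (anyDuplicated(paste(gc[, 1L], gc[, 2L])))
        msg <- c(msg, "grid positions must be unique")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' WeightedRelation: a reflexive (optionally symmetric) weighted relation
#'
#' A weighted relation on a finite index set assigns each ordered pair a
#' strength in \[0, 1\], stored as a square matrix with unit diagonal
#' (reflexivity). By default the relation is required to be symmetric;
#' asymmetric relations can be represented by constructing with
#' `symmetric = FALSE`, which relaxes the validity check only.
#'
#' The index set is either the system's nodes (a relation `R`) or the
#' node repertoire (a relation `U`); the class does not distinguish the
#' two roles.
#'
#' @slot labels character vector of index labels.
#' @slot values numeric square matrix of strengths in \[0, 1\].
#' @slot symmetric logical scalar; if `TRUE` (default) validity enforces
#'   symmetry to within 1e-9.
#'
#' @examples
#' constantRelation(letters[1:3])
#' @exportClass WeightedRelation
setClass("WeightedRelation",
  representation(labels = "character", values = "matrix",
                 symmetric = "logical"))

setValidity("WeightedRelation", function(object) {
  v <- object@values
  msg <- NULL
  if (nrow(v) != ncol(v))
    msg <- c(msg, "relation matrix must be square")
  if (length(object@labels) != nrow(v))
    msg <- c(msg, "labels must match matrix dimension")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "relation labels must be unique")
  if (!is.numeric(v) || anyNA(v))
    msg <- c(msg, "relation entries must be numeric and non-missing")
  else {
    if (any(v < 0 | v > 1))
      msg <- c(msg, "relation entries must lie in [0, 1]")
    if (nrow(v) == ncol(v) && any(abs(diag(v) - 1) > 0))
      msg <- c(msg, "relation must be reflexive (unit diagonal)")
    if (isTRUE(object@symmetric) && nrow(v) == ncol(v) &&
        any(abs(v - t(v)) > 1e-9))
      msg <- c(msg, "relation matrix is asymmetric beyond 1e-9")
  }
  if (is.null(msg)) TRUE else msg
})

#' TypicalData: numbered observations of the system's state
#'
#' The typical data is a numbered sequence of complete observations
#' (data elements), possibly with repeats: observation k assigns each
#' node one state from the shared repertoire. States are stored as
#' 1-based integer indices into the repertoire.
#'
#' @slot states integer matrix, one row per observation, one column per
#'   node (colnames = node ids); entries in `1..m`.
#' @slot layout the [SystemLayout-class] all observations share.
#' @slot repertoire character vector of the m distinct state labels, in
#'   the fixed order that defines the state indices.
#'
#' @exportClass TypicalData
setClass("TypicalData",
  representation(states = "matrix", layout = "SystemLayout",
                 repertoire = "character"))

setValidity("TypicalData", function(object) {
  msg <- NULL
  s <- object@states
  if (nrow(s) < 1L) msg <- c(msg, "typical data must contain >= 1 observation")
  if (!identical(colnames(s), object@layout@nodeIds))
    msg <- c(msg, "state columns must match the layout's node ids")
  m <- length(object@repertoire)
  if (m < 1L) msg <- c(msg, "repertoire must be nonempty")
  if (anyDuplicated(object@repertoire))
    msg <- c(msg, "repertoire labels must be unique")
  if (anyNA(s) || (length(s) && (any(s < 1L) || any(s > m))))
    msg <- c(msg, "state indices must lie in 1..m with no missing values")
  if (is.null(msg)) TRUE else msg
})

#' StateSpace: the canonical enumeration of all m^n data elements
#'
#' Enumerates the full state space of an n-node system with an m-state
#' repertoire in lexicographic order (node order = layout order, first
#' node most significant), giving a reproducible bijection between
#' 1-based state indices and state vectors. An optional probability
#' vector over the states turns the space into a probability space.
#'
#' @slot n integer, number of nodes.
#' @slot m integer, repertoire size.
#' @slot size numeric, m^n.
#' @slot prob numeric; either length 0 (no distribution attached) or a
#'   probability vector of length m^n.
#'
#' @exportClass StateSpace
setClass("StateSpace",
  representation(n = "integer", m = "integer", size = "numeric",
                 prob = "numeric"))

setValidity("StateSpace", function(object) {
  msg <- NULL
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (abs(object@size - as.numeric(object@m)^object@n) > 0.5)
    msg <- c(msg, "size must equal m^n")
  p <- object@prob
  if (length(p)) {
    if (length(p) != object@size)
      msg <- c(msg, "prob must have one entry per state")
    else if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "prob must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (is.null(msg)) TRUE else msg
})

#' EfeResult: a float-entropy evaluation
#'
#' @slot efe numeric scalar, the expected float entropy in bits per data
#'   element (bpe).
#' @slot perElementFe numeric vector of per-observation (or per-state)
#'   float entropies in bpe.
#' @slot weights numeric; the probabilities (exact case) or the implicit
#'   1/#T weights (empirical case) applied to `perElementFe`.
#'
#' @exportClass EfeResult
setClass("EfeResult",
  representation(efe = "numeric", perElementFe = "numeric",
                 weights = "numeric"))

#' EfeHistogram: a Monte-Carlo null distribution of efe values
#'
#' Holds efe values computed at independent uniformly random relation
#' pairs, binned at a fixed interval, together with an optional marker
#' (a candidate solution's efe) and its percentile rank among the
#' samples.
#'
#' @slot samples numeric vector of efe draws (bpe).
#' @slot binWidth numeric scalar.
#' @slot binLeft numeric vector of left bin edges.
#' @slot counts integer vector of bin counts.
#' @slot marker numeric; length 0 when no candidate was supplied.
#' @slot markerPercentile numeric; percentage of samples <= marker.
#'
#' @exportClass EfeHistogram
setClass("EfeHistogram",
  representation(samples = "numeric", binWidth = "numeric",
                 binLeft = "numeric", counts = "integer",
                 marker = "numeric", markerPercentile = "numeric"))

#' StatePartition: greedy partition of the state space
#'
#' The partition produced by the greedy seeding procedure used to recast
#' expected float entropy as a conditional Shannon entropy: blocks are
#' grown around unallocated states of maximal probability, each block
#' collecting the still-unallocated states whose distance profile does
#' not exceed the seed's.
#'
#' @slot blocks list of integer vectors of 1-based state indices,
#'   pairwise disjoint.
#' @slot seeds integer vector, the seed state of each block.
#' @slot covered character, either "support" or "all", recording whether
#'   the partition covers only states of positive probability.
#'
#' @exportClass StatePartition
setClass("StatePartition",
  representation(blocks = "list", seeds = "integer", covered = "character"))

#' CompletionResult: minimum-float-entropy completions of one observation
#'
#' @slot completions integer matrix, one row per tied minimum-fe
#'   completion (columns = nodes, 1-based state indices).
#' @slot minFe numeric, the common float entropy of the tied completions
#'   (bpe).
#' @slot candidateCount numeric, m^k, the number of candidates examined.
#' @slot hiddenNodes character, the obfuscated node ids.
#'
#' @exportClass CompletionResult
setClass("CompletionResult",
  representation(completions = "matrix", minFe = "numeric",
                 candidateCount = "numeric", hiddenNodes = "character"))
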