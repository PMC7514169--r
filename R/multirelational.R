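#' Default tuple nodes for a 3x3 grid
#'
#' The eight collinear triples of a 3x3 grid — three rows, three
#' columns and the two main diagonals — used as derived nodes for
#' multi-relational float entropy. Minimising the multi-level objective
#' then rewards strong relations between parallel line structures.
#' Other layouts require an explicit tuple specification.
#'
#' @param layout a [SystemLayout-class] with 3x3 grid coordinates.
#' @return a list of 8 character triples of node ids.
#' @export
defaultGridTuples <- function(layout) {
  gc <- gridCoords(layout)
  if (is.null(gc) || nrow(gc) != 9L ||
      max(gc[, 1L]) - min(gc[, 1L]) != 2L ||
      max(gc[, 2L]) - min(gc[, 2L]) != 2L)
    stop("default tuples are defined for 3x3 grids only; ",
         "specify tuples explicitly for other layouts")
  ids <- nodeIds(layout)
  r <- gc[, 1L] - min(gc[, 1L]) + 1L
  c <- gc[, 2L] - min(gc[, 2L]) + 1L
  byPos <- ids[order(r, c)]
  g <- matrix(byPos, 3L, 3L, byrow = TRUE)
  out <- c(lapply(1:3, function(i) g[i, ]),
           lapply(1:3, function(j) g[, j]),
           list(c(g[1, 1], g[2, 2], g[3, 3])),
           list(c(g[1, 3], g[2, 2], g[3, 1])))
  lapply(out, as.character)
}

#' Reduce a tuple of base states to the three-state derived repertoire
#'
#' A tuple is in derived state 1 when all its base states coincide; in
#' state 2 when they are not all the same but pairwise strongly related
#' according to U (every distinct unordered pair has U >= theta); and in
#' state 3 otherwise. The rule is invariant under permutation of the
#' tuple.
#'
#' @param states integer vector of 1-based base state indices.
#' @param U the base repertoire [WeightedRelation-class].
#' @param theta strength threshold for "strongly related" (default 0.2).
#' @return integer in 1..3.
#' @export
reduceTupleState <- function(states, U, theta = 0.2) {
  u <- unique(states)
  if (length(u) == 1L) return(1L)
  uv <- relationMatrix(U)
  pr <- utils::combn(u, 2L)
  if (all(uv[t(pr)] >= theta)) 2L else 3L
}

# reduced state of every base-state combination of one tuple, in
# mixed-radix big-endian order (0-based table for the C++ kernel)
tupleReductionTable <- function(arity, m, U, theta = 0.2) {
  combos <- decodeState(StateSpace(arity, m), seq_len(as.numeric(m)^arity))
  vapply(seq_len(nrow(combos)), function(j)
    reduceTupleState(combos[j, ], U, theta), integer(1)) - 1L
}

#' Derived data element over tuple nodes
#'
#' @param element named integer vector of base states (names = node
#'   ids).
#' @param tuples list of character tuples of node ids.
#' @param U base repertoire relation used by the reduction rule.
#' @param theta strength threshold (default 0.2).
#' @return named integer vector of derived states in 1..3, one per
#'   tuple.
#' @export
derivedElement <- function(element, tuples, U, theta = 0.2) {
  out <- vapply(tuples, function(tp)
    reduceTupleState(element[tp], U, theta), integer(1))
  names(out) <- paste0("tuple", seq_along(tuples))
  out
}

#' Derived typical data over tuple nodes
#'
#' Maps every observation to its derived element, yielding typical data
#' over the tuple nodes with the reduced three-state repertoire — the
#' input for learning a second-level relation pair with
#' [minimiseEfe()].
#'
#' @param T base [TypicalData-class].
#' @param tuples list of character tuples of node ids.
#' @param U base repertoire relation used by the reduction rule.
#' @param theta strength threshold (default 0.2).
#' @return a [TypicalData-class] over the derived nodes with repertoire
#'   `c("v1", "v2", "v3")`.
#' @export
derivedTypicalData <- function(T, tuples, U, theta = 0.2) {
  s <- stateMatrix(T)
  out <- t(apply(s, 1L, derivedElement, tuples = tuples, U = U,
                 theta = theta))
  colnames(out) <- paste0("tuple", seq_along(tuples))
  TypicalData(out, repertoire = c("v1", "v2", "v3"))
}

#' Specify one condition level for multi-relational float entropy
#'
#' The base level (level 0) carries the node relation R and repertoire
#' relation U of ordinary float entropy. Each further level carries a
#' relation pair over derived tuple nodes and their reduced repertoire,
#' plus the tuple definition and the reduction threshold; the reduction
#' always reads the base-level U.
#'
#' @param R,U [WeightedRelation-class]s for this level.
#' @param tuples `NULL` for the base level, else a list of node-id
#'   tuples.
#' @param theta reduction threshold (derived levels; default 0.2).
#' @return a list usable in the `conditions` argument of [multiFe()].
#' @export
conditionLevel <- function(R, U, tuples = NULL, theta = 0.2) {
  list(R = R, U = U, tuples = tuples, theta = theta)
}

# distance profiles for every condition level, as a column-per-level matrix
conditionProfiles <- function(conditions, space) {
  base <- conditions[[1L]]
  if (!is.null(base$tuples)) stop("the first condition must be the base level")
  profs <- matrix(0, nrow = space@size, ncol = length(conditions))
  profs[, 1L] <- cpp_distance_profile(space@n, space@m,
                                      relationMatrix(base$R),
                                      relationMatrix(base$U))
  if (length(conditions) > 1L)
    for (l in 2:length(conditions)) {
      lv <- conditions[[l]]
      tuples0 <- lapply(lv$tuples, function(tp)
        match(tp, relationLabels(base$R)) - 1L)
      if (anyNA(unlist(tuples0)))
        stop("tuple member is not a base node")
      red <- lapply(lv$tuples, function(tp)
        tupleReductionTable(length(tp), space@m, base$U, lv$theta))
      profs[, l] <- cpp_derived_profile(space@n, space@m, tuples0, red,
                                        relationMatrix(lv$R),
                                        relationMatrix(lv$U))
    }
  profs
}

#' Multi-relational float entropy
#'
#' Counts the base states that satisfy every condition level
#' simultaneously — at each level, the state's induced relation must lie
#' no farther from that level's R than the queried element's does — and
#' takes log2. With the base condition alone this reduces exactly to
#' ordinary float entropy; every added condition can only shrink the
#' counting set, so the value is monotonically non-increasing in the
#' number of conditions.
#'
#' @param conditions list of [conditionLevel()]s, the first being the
#'   base level.
#' @param element named integer state vector(s) (or use `index`).
#' @param space the base [StateSpace-class].
#' @param index alternative 1-based state indices.
#' @return numeric vector of multi-relational float entropies, bpe.
#' @export
multiFe <- function(conditions, element = NULL, space, index = NULL) {
  profs <- conditionProfiles(conditions, space)
  if (is.null(index)) {
    if (is.null(element)) stop("supply element or index")
    if (is.null(dim(element)))
      element <- matrix(element, nrow = 1L, dimnames = list(NULL, names(element)))
    element <- element[, relationLabels(conditions[[1L]]$R), drop = FALSE]
    index <- encodeState(space, element)
  }
  log2(cpp_count_le_joint(profs, as.integer(index - 1L)))
}

#' Expected multi-relational float entropy over typical data
#'
#' @param conditions list of [conditionLevel()]s.
#' @param T base [TypicalData-class].
#' @return an [EfeResult-class].
#' @export
multiEfe <- function(conditions, T) {
  if (nObservations(T) < 1L) stop("typical data is empty")
  space <- StateSpace(ncol(stateMatrix(T)), length(repertoire(T)))
  fe <- multiFe(conditions, element = stateMatrix(T), space = space)
  new("EfeResult", efe = mean(fe), perElementFe = fe,
      weights = rep(1 / length(fe), length(fe)))
}
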