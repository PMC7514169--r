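#' Distance profile of a relation pair over the state space
#'
#' For every data element S_j of the enumerated state space, computes
#' the d1 distance between R and the relation S_j induces from U,
#' summed over all ordered node pairs (diagonal included). The profile
#' is the only quantity float entropy depends on: the float entropy of
#' any element is log2 of the number of states whose profile entry does
#' not exceed its own.
#'
#' The default engine tabulates, per ordered node pair, the m^2 costs
#' |R(a,b) - U(s,t)| and accumulates them over the mixed-radix
#' enumeration in C++; the "reference" engine is a plain R loop over
#' [inducedRelation()] and [relationDistance()], kept for cross-checking
#' on small systems.
#'
#' @param R a [WeightedRelation-class] over the nodes (dimension n).
#' @param U a [WeightedRelation-class] over the repertoire (dimension m).
#' @param space a [StateSpace-class] with matching n and m.
#' @param engine "cpp" (default) or "reference".
#' @return numeric vector of length m^n, in canonical state order.
#' @export
distanceProfile <- function(R, U, space, engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  rv <- relationMatrix(R)
  uv <- relationMatrix(U)
  if (nrow(rv) != space@n) stop("R dimension must equal n")
  if (nrow(uv) != space@m) stop("U dimension must equal m")
  if (engine == "cpp")
    return(cpp_distance_profile(space@n, space@m, rv, uv,
                                symmetric = R@symmetric && U@symmetric))
  states <- enumerateStates(space)
  labs <- relationLabels(R)
  vapply(seq_len(nrow(states)), function(j) {
    relationDistance(R, inducedRelation(U, states[j, ], labs), order = 1)
  }, numeric(1))
}

# <=-counts against a profile; `sorted` may be passed to amortise the sort
feCounts <- function(profile, indices, tol = 0, sorted = NULL) {
  if (is.null(sorted)) sorted <- sort(profile)
  findInterval(profile[indices] + tol, sorted)
}

#' Float entropy of a data element
#'
#' The float entropy of element S_i, relative to relations R (on nodes)
#' and U (on the repertoire), is log2 of the number of states S_j whose
#' induced relation lies no farther from R (in d1) than S_i's does.
#' It is measured in bits per data element (bpe) and lies in
#' \[0, n log2 m\]; every element counts itself, so the count is >= 1.
#'
#' Ties in distance are counted with `<=`, exactly as the definition
#' dictates (this is what keeps the everywhere-1 constant relations from
#' being a trivial minimiser). The comparison is exact on the computed
#' doubles; `tol` (default 0) can widen the count window.
#'
#' @param R,U weighted relations as in [distanceProfile()].
#' @param element a state vector (1-based indices), a matrix of state
#'   vectors, or `NULL` to use `index`.
#' @param space a [StateSpace-class].
#' @param profile optional precomputed [distanceProfile()] (computed on
#'   the fly when omitted).
#' @param index alternative to `element`: 1-based state indices.
#' @param tol comparison tolerance for the `<=` count (default 0, exact).
#' @return numeric vector of float entropies, bpe.
#' @export
floatEntropy <- function(R, U, element = NULL, space, profile = NULL,
                         index = NULL, tol = 0) {
  if (is.null(profile)) profile <- distanceProfile(R, U, space)
  if (is.null(index)) {
    if (is.null(element)) stop("supply element or index")
    index <- encodeState(space, element)
  }
  log2(feCounts(profile, index, tol = tol))
}

#' Empirical expected float entropy over typical data
#'
#' The empirical efe is the mean float entropy over the numbered
#' observations of the typical data, repeats weighted by multiplicity.
#'
#' @param R,U weighted relations as in [distanceProfile()].
#' @param T a [TypicalData-class].
#' @param space optional [StateSpace-class] (constructed from T when
#'   omitted).
#' @param profile optional precomputed distance profile.
#' @param tol comparison tolerance passed to the `<=` count.
#' @return an [EfeResult-class]; `efeValue()` is in bpe.
#' @examples
#' T <- TypicalData(matrix(c(1L, 2L, 2L, 1L), 2, 2), repertoire = c("a", "b"))
#' efeValue(efeEmpirical(constantRelation(paste0("node", 1:2)),
#'                       constantRelation(c("a", "b")), T))
#' @export
efeEmpirical <- function(R, U, T, space = NULL, profile = NULL, tol = 0) {
  if (nObservations(T) < 1L) stop("typical data is empty")
  if (is.null(space))
    space <- StateSpace(ncol(stateMatrix(T)), length(repertoire(T)))
  if (is.null(profile)) profile <- distanceProfile(R, U, space)
  idx <- encodeState(space, stateMatrix(T))
  fe <- log2(feCounts(profile, idx, tol = tol))
  new("EfeResult", efe = mean(fe), perElementFe = fe,
      weights = rep(1 / length(fe), length(fe)))
}

#' Exact expected float entropy under a state distribution
#'
#' The probability-weighted mean of the float entropy over the whole
#' state space. When the distribution is the empirical distribution of
#' a typical data set this coincides exactly with [efeEmpirical()].
#'
#' @param R,U weighted relations as in [distanceProfile()].
#' @param space a [StateSpace-class] carrying a probability vector (see
#'   [empiricalDistribution()] or `stateProb<-`).
#' @param profile optional precomputed distance profile.
#' @param tol comparison tolerance passed to the `<=` count.
#' @return an [EfeResult-class] whose `perElementFe` covers every state
#'   and whose `weights` are the probabilities.
#' @export
efeExact <- function(R, U, space, profile = NULL, tol = 0) {
  p <- stateProb(space)
  if (!length(p)) stop("state space carries no probability vector")
  if (is.null(profile)) profile <- distanceProfile(R, U, space)
  sorted <- sort(profile)
  fe <- log2(findInterval(profile + tol, sorted))
  new("EfeResult", efe = sum(p * fe), perElementFe = fe, weights = p)
}

#' @rdname EfeResult-class
#' @export
setMethod("efeValue", "EfeResult", function(object) object@efe)

#' @rdname EfeResult-class
#' @export
setMethod("feValues", "EfeResult", function(object) object@perElementFe)

setMethod("show", "EfeResult", function(object) {
  cat("EfeResult: efe =", format(object@efe, digits = 6), "bpe over",
      length(object@perElementFe), "elements\n")
})
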