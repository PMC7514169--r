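#' Shannon entropy of a state distribution
#'
#' -sum(p log2 p) over the support, in bits.
#'
#' @param p a probability vector, or a [StateSpace-class] carrying one.
#' @return entropy in bits.
#' @export
shannonEntropy <- function(p) {
  if (is(p, "StateSpace")) p <- stateProb(p)
  if (!length(p)) stop("no probability vector")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a normalised probability vector")
  pp <- p[p > 0]
  -sum(pp * log2(pp))
}

#' Greedy partition of the state space from a relation pair
#'
#' Builds the partition that recasts expected float entropy as a
#' conditional Shannon entropy. Repeatedly: among the states not yet
#' allocated, take as seed the one of greatest probability (ties broken
#' by the smallest `<=`-count #A, then by canonical state index); the
#' next block is the set of still-unallocated states whose distance
#' profile does not exceed the seed's. The tie structure makes this well
#' defined: candidate seeds with equal #A have identical A sets.
#'
#' When `support = TRUE` (default) only states of positive probability
#' are partitioned, which leaves the conditional entropy unchanged.
#'
#' @param space a [StateSpace-class] with a probability vector.
#' @param R,U weighted relations as in [distanceProfile()].
#' @param profile optional precomputed distance profile.
#' @param support restrict to states with P > 0 (default TRUE).
#' @return a [StatePartition-class].
#' @export
statePartition <- function(space, R, U, profile = NULL, support = TRUE) {
  p <- stateProb(space)
  if (!length(p)) stop("state space carries no probability vector")
  if (is.null(profile)) profile <- distanceProfile(R, U, space)
  consider <- if (support) which(p > 0) else seq_along(p)
  prof <- profile[consider]
  pc <- p[consider]
  aSize <- findInterval(prof, sort(prof))
  unalloc <- rep(TRUE, length(consider))
  blocks <- list()
  seeds <- integer(0)
  while (any(unalloc)) {
    cand <- which(unalloc)
    cand <- cand[pc[cand] == max(pc[cand])]
    if (length(cand) > 1L) cand <- cand[aSize[cand] == min(aSize[cand])]
    seed <- cand[1L]
    block <- which(unalloc & prof <= prof[seed])
    unalloc[block] <- FALSE
    blocks[[length(blocks) + 1L]] <- consider[block]
    seeds <- c(seeds, consider[seed])
  }
  new("StatePartition", blocks = blocks, seeds = as.integer(seeds),
      covered = if (support) "support" else "all")
}

#' @rdname StatePartition-class
#' @export
setMethod("partitionBlocks", "StatePartition", function(object) object@blocks)

#' @rdname StatePartition-class
#' @export
setMethod("partitionSeeds", "StatePartition", function(object) object@seeds)

setMethod("show", "StatePartition", function(object) {
  cat("StatePartition:", length(object@blocks), "block(s) covering",
      length(unlist(object@blocks)), "state(s) (", object@covered, ")\n")
})

#' Conditional entropy of the state given its partition block
#'
#' Under the joint distribution P(S_i, A) = P(S_i) for S_i in A (0
#' otherwise), the conditional entropy H(state | block) is
#' sum over blocks A, states i in A of P(S_i) log2(P(A) / P(S_i)).
#' It lies in \[0, H(P)\]: a one-block partition gives H(P), singleton
#' blocks give 0.
#'
#' @param space a [StateSpace-class] with probability vector.
#' @param partition a [StatePartition-class] covering the support.
#' @return bits.
#' @export
conditionalEntropy <- function(space, partition) {
  p <- stateProb(space)
  if (!length(p)) stop("state space carries no probability vector")
  covered <- unlist(partitionBlocks(partition))
  if (any(p[setdiff(seq_along(p), covered)] > 0))
    stop("partition does not cover the support of P")
  h <- 0
  for (block in partitionBlocks(partition)) {
    pb <- p[block]
    pa <- sum(pb)
    pb <- pb[pb > 0]
    if (length(pb)) h <- h + sum(pb * log2(pa / pb))
  }
  h
}

#' Conditional-entropy-style surrogate decomposition of efe
#'
#' Computes the conditional-entropy-like functional
#' sum_i P(S_i) log2( P(A_i) / P(S_i) ), where A_i is the set of states
#' whose distance profile does not exceed S_i's, both directly and via
#' its decomposition H + sum_i P(S_i) log2 P(A_i) (the second term lies
#' in \[-H, 0\]). For everywhere-1 constant relations every A_i is the
#' whole space and the surrogate equals the Shannon entropy exactly.
#' The exact efe is reported alongside for comparison.
#'
#' @param space a [StateSpace-class] with probability vector.
#' @param R,U weighted relations as in [distanceProfile()].
#' @param profile optional precomputed distance profile.
#' @return a list: `surrogate`, `H`, `secondTerm`, `viaDecomposition`
#'   (= H + secondTerm) and `efe`.
#' @export
efeSurrogate <- function(space, R, U, profile = NULL) {
  p <- stateProb(space)
  if (!length(p)) stop("state space carries no probability vector")
  if (is.null(profile)) profile <- distanceProfile(R, U, space)
  ord <- order(profile)
  cum <- cumsum(p[ord])
  sorted <- profile[ord]
  pa <- cum[findInterval(profile, sorted)]
  sup <- p > 0
  surrogate <- sum(p[sup] * log2(pa[sup] / p[sup]))
  H <- shannonEntropy(p)
  second <- sum(p[sup] * log2(pa[sup]))
  list(surrogate = surrogate, H = H, secondTerm = second,
       viaDecomposition = H + second,
       efe = efeValue(efeExact(R, U, space, profile = profile)))
}

#' Export a state partition as JSON
#'
#' @param partition a [StatePartition-class].
#' @param path output path.
#' @export
writeStatePartition <- function(partition, path) {
  jsonlite::write_json(list(blocks = partitionBlocks(partition),
                            seeds = partitionSeeds(partition),
                            covered = partition@covered),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
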