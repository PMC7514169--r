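#' @rdname StateSpace-class
#' @param n number of nodes.
#' @param m repertoire size.
#' @param prob optional probability vector over the m^n states.
#' @param sizeCap refuse to enumerate spaces larger than this many
#'   states (default 2^21); exhaustive float-entropy computation scales
#'   linearly in the space size, so larger systems should be analysed on
#'   a node subset instead.
#' @return `StateSpace()` returns a [StateSpace-class].
#' @examples
#' ss <- StateSpace(9, 4)
#' nStates(ss)  # 262144
#' decodeState(ss, 1)
#' @export
StateSpace <- function(n, m, prob = numeric(0), sizeCap = 2^21) {
  n <- as.integer(n); m <- as.integer(m)
  size <- as.numeric(m)^n
  if (size > sizeCap)
    stop("state space has ", format(size, big.mark = ","), " states, above ",
         "the cap of ", format(sizeCap, big.mark = ","),
         "; analyse a node subset or raise sizeCap")
  new("StateSpace", n = n, m = m, size = size, prob = as.numeric(prob))
}

#' @rdname StateSpace-class
#' @export
setMethod("nStates", "StateSpace", function(object) object@size)

#' @rdname StateSpace-class
#' @export
setMethod("stateProb", "StateSpace", function(object) object@prob)

#' @rdname StateSpace-class
#' @export
setReplaceMethod("stateProb", "StateSpace", function(object, value) {
  object@prob <- as.numeric(value)
  validObject(object)
  object
})

setMethod("show", "StateSpace", function(object) {
  cat("StateSpace: n =", object@n, "nodes, m =", object@m,
      "states/node,", format(object@size, big.mark = ","), "states",
      if (length(object@prob)) "(with probability vector)" else "", "\n")
})

#' Encode and decode canonical state indices
#'
#' The canonical enumeration is lexicographic with the first node most
#' significant (big-endian mixed radix): state vector `s` (1-based
#' entries in 1..m) maps to index `1 + sum((s - 1) * m^(n - a))`.
#'
#' @param space a [StateSpace-class].
#' @param state integer vector of length n with entries in 1..m, or a
#'   matrix with one such row per state.
#' @return `encodeState` returns 1-based state indices; `decodeState`
#'   returns an integer matrix of state vectors (one row per index).
#' @export
encodeState <- function(space, state) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  n <- space@n; m <- as.numeric(space@m)
  if (ncol(state) != n) stop("state vector length must equal n")
  if (any(state < 1L) || any(state > space@m))
    stop("state entries must lie in 1..m")
  pw <- m^((n - 1L):0L)
  as.numeric((state - 1L) %*% pw) + 1
}

#' @rdname encodeState
#' @param index 1-based state index or vector of indices.
#' @export
decodeState <- function(space, index) {
  n <- space@n; m <- as.numeric(space@m)
  if (any(index < 1) || any(index > space@size))
    stop("state index out of range")
  j <- as.numeric(index) - 1
  out <- matrix(0L, nrow = length(j), ncol = n)
  for (a in n:1L) {
    out[, a] <- as.integer(j %% m) + 1L
    j <- j %/% m
  }
  colnames(out) <- NULL
  out
}

#' Enumerate every state vector of a (small) state space
#'
#' Materialises the full m^n x n matrix of state vectors in canonical
#' order. Intended for small systems; the float-entropy engine itself
#' never materialises this matrix.
#'
#' @param space a [StateSpace-class].
#' @return integer matrix with m^n rows.
#' @export
enumerateStates <- function(space) {
  decodeState(space, seq_len(space@size))
}
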