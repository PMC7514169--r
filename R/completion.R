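#' Obfuscate an observation by deleting node states
#'
#' Chooses `k` of the nodes uniformly at random (without replacement)
#' and deletes their state information. Draws from the current RNG
#' stream; set a seed for reproducibility.
#'
#' @param element named integer vector of 1-based state indices (names =
#'   node ids), e.g. a row of [stateMatrix()].
#' @param k number of nodes to hide (0 <= k <= n).
#' @return a list with class "ObfuscatedElement": `known` (named states
#'   of the observed nodes), `hiddenNodes` (character) and `nodes` (all
#'   node ids in layout order).
#' @export
obfuscate <- function(element, k) {
  nodes <- names(element)
  if (is.null(nodes)) stop("element must carry node names")
  n <- length(nodes)
  if (k < 0 || k > n) stop("k must lie in 0..n")
  hidden <- if (k > 0) sort(sample.int(n, k)) else integer(0)
  structure(list(known = element[setdiff(seq_len(n), hidden)],
                 hiddenNodes = nodes[hidden], nodes = nodes),
            class = "ObfuscatedElement")
}

#' Enumerate all completions of an obfuscated observation
#'
#' There are m^k candidate completions, one per assignment of repertoire
#' states to the k hidden nodes; all preserve the known states. The
#' candidates are returned in lexicographic order over the hidden-node
#' assignments (hidden nodes in layout order, first hidden node most
#' significant).
#'
#' @param obf an "ObfuscatedElement" from [obfuscate()].
#' @param m repertoire size.
#' @return integer matrix, m^k rows, columns = all nodes in layout
#'   order.
#' @export
enumerateCompletions <- function(obf, m) {
  nodes <- obf$nodes
  k <- length(obf$hiddenNodes)
  nc <- as.numeric(m)^k
  out <- matrix(0L, nrow = nc, ncol = length(nodes),
                dimnames = list(NULL, nodes))
  for (nm in names(obf$known)) out[, nm] <- obf$known[[nm]]
  if (k > 0) {
    hid <- decodeState(StateSpace(k, m), seq_len(nc))
    out[, obf$hiddenNodes] <- hid
  }
  out
}

#' Minimum-float-entropy completion
#'
#' Among the m^k completions of an obfuscated observation, returns every
#' candidate whose float entropy under (R, U) attains the minimum. Ties
#' are all kept: an obfuscated observation can genuinely admit more than
#' one minimum-fe completion.
#'
#' @param R,U the learned [WeightedRelation-class]s.
#' @param obf an "ObfuscatedElement".
#' @param space a [StateSpace-class].
#' @param profile optional precomputed [distanceProfile()]; pass it when
#'   completing many observations under one relation pair.
#' @param feAll optional precomputed vector of float entropies for every
#'   state (log2 of the `<=`-counts), overriding `profile`.
#' @return a [CompletionResult-class].
#' @export
minFeComplete <- function(R, U, obf, space, profile = NULL, feAll = NULL) {
  cand <- enumerateCompletions(obf, space@m)
  idx <- encodeState(space, cand)
  if (is.null(feAll)) {
    if (is.null(profile)) profile <- distanceProfile(R, U, space)
    fe <- log2(feCounts(profile, idx))
  } else fe <- feAll[idx]
  best <- fe == min(fe)
  new("CompletionResult", completions = cand[best, , drop = FALSE],
      minFe = min(fe), candidateCount = nrow(cand),
      hiddenNodes = obf$hiddenNodes)
}

setMethod("show", "CompletionResult", function(object) {
  cat("CompletionResult:", nrow(object@completions), "tied completion(s)",
      "of", length(object@hiddenNodes), "hidden node(s) out of",
      object@candidateCount, "candidates; min fe =",
      format(object@minFe, digits = 5), "bpe\n")
})

#' Score completions against the ground truth
#'
#' For each observation the number of hidden nodes completed correctly
#' is counted; when an observation has several tied minimum-fe
#' completions, the average count across the ties is used and rounded
#' down when not an integer (the per-observation recorded count feeding
#' the histogram). The summary mean is computed from the unrounded
#' per-observation averages; both are reported.
#'
#' @param results list of [CompletionResult-class] (or plain completed
#'   integer matrices/vectors), one per observation.
#' @param truth integer matrix of the true observations (rows aligned
#'   with `results`, columns named by node).
#' @param hidden list of character vectors, the hidden node ids per
#'   observation (taken from the results when they are
#'   CompletionResults).
#' @return a list: `recorded` (per-observation floored counts), `meanCorrect`
#'   (mean of unrounded averages), `meanRecorded`, `totalCorrect` (sum of
#'   recorded counts), `proportions` (named vector over 0..k), `k`,
#'   `nObservations` and `ties` (observations with > 1 tied completion).
#' @export
evaluateCompletions <- function(results, truth, hidden = NULL) {
  if (length(results) != nrow(truth))
    stop("results and truth are misaligned")
  nObs <- length(results)
  avg <- numeric(nObs)
  recorded <- numeric(nObs)
  ties <- 0L
  ks <- integer(nObs)
  for (i in seq_len(nObs)) {
    r <- results[[i]]
    if (is(r, "CompletionResult")) {
      comp <- r@completions
      hid <- r@hiddenNodes
    } else {
      comp <- if (is.null(dim(r))) matrix(r, nrow = 1L,
                                          dimnames = list(NULL, names(r)))
              else r
      hid <- hidden[[i]]
    }
    ks[i] <- length(hid)
    if (nrow(comp) > 1L) ties <- ties + 1L
    cc <- vapply(seq_len(nrow(comp)), function(j)
      sum(comp[j, hid] == truth[i, hid]), numeric(1))
    avg[i] <- mean(cc)
    recorded[i] <- floor(avg[i])
  }
  k <- max(ks)
  props <- as.numeric(table(factor(recorded, levels = 0:k))) / nObs
  names(props) <- 0:k
  list(recorded = recorded, meanCorrect = mean(avg),
       meanRecorded = mean(recorded), totalCorrect = sum(recorded),
       proportions = props, k = k, nObservations = nObs, ties = ties)
}

#' Independent per-node mode baseline
#'
#' The baseline completes each hidden node independently with the most
#' commonly observed state for that node in the training data; modal
#' ties are broken towards the lowest state index.
#'
#' @param T training [TypicalData-class].
#' @return a function taking an "ObfuscatedElement" and returning the
#'   completed named integer vector; its `modes` attribute carries the
#'   per-node modal states.
#' @export
independentModeBaseline <- function(T) {
  s <- stateMatrix(T)
  m <- length(repertoire(T))
  modes <- apply(s, 2L, function(col) {
    counts <- tabulate(col, nbins = m)
    which.max(counts)  # which.max takes the first (lowest) on ties
  })
  f <- function(obf) {
    out <- integer(length(obf$nodes))
    names(out) <- obf$nodes
    out[names(obf$known)] <- obf$known
    out[obf$hiddenNodes] <- modes[obf$hiddenNodes]
    out
  }
  attr(f, "modes") <- modes
  f
}

#' Uniform-guessing reference distribution
#'
#' When the k hidden states are guessed uniformly at random, the number
#' of correctly completed nodes is Binomial(k, 1/m), with expectation
#' k/m.
#'
#' @param k number of hidden nodes.
#' @param m repertoire size.
#' @return a list: `pmf` (named over 0..k) and `expectation`.
#' @export
guessingDistribution <- function(k, m) {
  if (k < 0 || m < 1) stop("need k >= 0 and m >= 1")
  pmf <- stats::dbinom(0:k, size = k, prob = 1 / m)
  names(pmf) <- 0:k
  list(pmf = pmf, expectation = k / m)
}

#' Tail probability of the total correct count under guessing
#'
#' For the total number of correct node states across a whole test set,
#' guessing gives a Binomial(total, p) count; the exact upper tail
#' P(X > threshold) is computed by summation, with the (continuity-
#' uncorrected) normal approximation N(total p, total p (1-p)) reported
#' alongside.
#'
#' @param total number of guessed node states across the test set.
#' @param p per-node success probability (1/m).
#' @param threshold observed total to beat.
#' @return a list: `exact` and `normalApprox` tail probabilities.
#' @export
guessingTail <- function(total, p, threshold) {
  if (total < 1 || p <= 0 || p >= 1) stop("need total >= 1 and p in (0,1)")
  list(exact = stats::pbinom(threshold, size = total, prob = p,
                             lower.tail = FALSE),
       normalApprox = stats::pnorm(threshold, mean = total * p,
                                   sd = sqrt(total * p * (1 - p)),
                                   lower.tail = FALSE))
}

#' Run a complete obfuscation/completion experiment
#'
#' Obfuscates every observation of the test data (k hidden nodes each,
#' drawn from the current RNG stream), completes them by minimum float
#' entropy and by the independent-mode baseline, and scores both against
#' the truth, alongside the uniform-guessing reference.
#'
#' @param R,U learned [WeightedRelation-class]s over the full system.
#' @param W test [TypicalData-class].
#' @param Ttrain training [TypicalData-class] (for the mode baseline).
#' @param k number of nodes hidden per observation.
#' @return a list: `minFe` and `mode` evaluation reports (see
#'   [evaluateCompletions()]), `guessing` (see
#'   [guessingDistribution()]), `guessingTailExact` for beating the
#'   min-fe total, and the per-observation `results`.
#' @export
runCompletionExperiment <- function(R, U, W, Ttrain, k) {
  space <- StateSpace(ncol(stateMatrix(W)), length(repertoire(W)))
  profile <- distanceProfile(R, U, space)
  sorted <- sort(profile)
  feAll <- log2(findInterval(profile, sorted))
  truth <- stateMatrix(W)
  baseline <- independentModeBaseline(Ttrain)
  results <- vector("list", nrow(truth))
  modeComp <- vector("list", nrow(truth))
  hidden <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    obf <- obfuscate(truth[i, ], k)
    hidden[[i]] <- obf$hiddenNodes
    results[[i]] <- minFeComplete(R, U, obf, space, feAll = feAll)
    modeComp[[i]] <- baseline(obf)
  }
  evMfe <- evaluateCompletions(results, truth)
  evMode <- evaluateCompletions(modeComp, truth, hidden = hidden)
  gd <- guessingDistribution(k, space@m)
  tail <- guessingTail(nrow(truth) * k, 1 / space@m, evMfe$totalCorrect)
  list(minFe = evMfe, mode = evMode, guessing = gd,
       guessingTailExact = tail$exact, results = results,
       hidden = hidden)
}
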