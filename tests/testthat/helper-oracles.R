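# Independent brute-force oracles, written from the definitions without
# touching the package's engines or its state enumeration.

# all state vectors of an n-node, m-state system in canonical order
# (first node most significant), built with expand.grid
oracleStates <- function(n, m) {
  eg <- expand.grid(rep(list(seq_len(m)), n))
  as.matrix(eg)[, n:1, drop = FALSE]
}

# d1 distance between R and the relation induced by state vector s,
# summed over all ordered pairs including the diagonal
oracleD1 <- function(Rmat, Umat, s) {
  n <- length(s)
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    acc <- acc + abs(Rmat[a, b] - Umat[s[a], s[b]])
  acc
}

oracleProfile <- function(Rmat, Umat, n, m) {
  st <- oracleStates(n, m)
  vapply(seq_len(nrow(st)), function(j) oracleD1(Rmat, Umat, st[j, ]),
         numeric(1))
}

# float entropy of the element equal to state-row `i` of the canonical
# enumeration, by exhaustive counting
oracleFe <- function(Rmat, Umat, n, m, s) {
  prof <- oracleProfile(Rmat, Umat, n, m)
  di <- oracleD1(Rmat, Umat, s)
  log2(sum(prof <= di))
}

# random reflexive symmetric relation with entries on the dyadic grid
# of odd multiples of 2^-depth: all d1 sums are then exact in binary,
# so cross-engine equality is exact equality
dyadicRelation <- function(labels, depth = 6L) {
  d <- length(labels)
  v <- matrix(0, d, d)
  up <- upper.tri(v)
  grid <- seq(1L, 2L^depth - 1L, by = 2L) / 2L^depth
  v[up] <- sample(grid, sum(up), replace = TRUE)
  v <- v + t(v)
  diag(v) <- 1
  WeightedRelation(labels, v)
}

# uniformly random relation (continuous entries)
contRelation <- function(labels) randomRelation(labels)

# typical data with given state rows
toyT <- function(rows, m, ids = paste0("node", seq_len(ncol(rows)))) {
  colnames(rows) <- ids
  TypicalData(rows, repertoire = paste0("s", seq_len(m)))
}

# the canonical study conditions, generated once per test run
studyCache <- new.env(parent = emptyenv())
studyData <- function() {
  if (is.null(studyCache$T)) {
    p <- fieldParams()
    studyCache$params <- p
    studyCache$T <- generateTypicalData(400, p, seed = 1)
    studyCache$W <- generateTypicalData(200, p, seed = 2)
  }
  studyCache
}
studyFit <- function() {
  sc <- studyData()
  if (is.null(sc$fit)) {
    sc$fit <- minimiseEfe(sc$T, depth = 6,
                          subset = c("node2", "node4", "node5",
                                     "node6", "node8"))
    sc$Rfull <- extendBySymmetry(sc$fit$R, systemLayout(sc$T))
  }
  sc
}
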