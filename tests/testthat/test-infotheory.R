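test_that("Shannon entropy matches closed forms", {
  expect_equal(shannonEntropy(c(0.5, 0.5)), 1)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(rep(1 / 8, 8)), 3)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.125, 0.125)), 1.75)
  ss <- StateSpace(2, 2, prob = rep(0.25, 4))
  expect_equal(shannonEntropy(ss), 2)
  expect_error(shannonEntropy(c(0.5, 0.6)), "normalised")
  expect_error(shannonEntropy(StateSpace(2, 2)), "no probability")
})

test_that("the greedy partition follows the seed and block rules", {
  # all distances equal: one block containing the whole support
  ss <- StateSpace(2, 2, prob = c(0.4, 0.3, 0.3, 0))
  Rc <- constantRelation(c("a", "b")); Uc <- constantRelation(c("s1", "s2"))
  part <- statePartition(ss, Rc, Uc)
  expect_length(partitionBlocks(part), 1L)
  expect_equal(sort(partitionBlocks(part)[[1]]), 1:3)
  expect_equal(partitionSeeds(part), 1L)  # highest probability seeds
  expect_equal(conditionalEntropy(ss, part), shannonEntropy(ss))

  # under uniform probability the seed rule picks the smallest counting
  # set each round, so the blocks are exactly the equal-profile groups
  # in increasing distance order (exact ties are inherent to the d1
  # metric: sums of absolute differences are locally constant)
  set.seed(41)
  R <- contRelation(c("a", "b", "c")); U <- contRelation(paste0("s", 1:3))
  ssu <- StateSpace(3, 3, prob = rep(1 / 27, 27))
  prof <- distanceProfile(R, U, ssu)
  pu <- statePartition(ssu, R, U)
  vals <- sort(unique(prof))
  expect_length(partitionBlocks(pu), length(vals))
  for (b in seq_along(vals))
    expect_equal(sort(partitionBlocks(pu)[[b]]), which(prof == vals[b]))
  # conditional entropy from the closed form over equal-profile groups
  sizes <- vapply(vals, function(v) sum(prof == v), numeric(1))
  expect_equal(conditionalEntropy(ssu, pu), sum(sizes / 27 * log2(sizes)))

  # hand trace: putting most probability on the largest-distance state
  # seeds it first, sweeping every support state into the first block
  ord <- order(prof)
  p2 <- numeric(27)
  p2[ord] <- c(rep(0.1, 5), rep(0, 21), 0.5)
  p3 <- statePartition(StateSpace(3, 3, prob = p2), R, U)
  expect_equal(partitionSeeds(p3)[1], ord[27])
  expect_length(partitionBlocks(p3), 1L)
  expect_equal(sort(partitionBlocks(p3)[[1]]), sort(ord[c(1:5, 27)]))
})

test_that("conditional entropy matches a hand computation and its bounds", {
  # blocks {1,2} and {3}, P = (0.25, 0.25, 0.5):
  # 0.25*log2(0.5/0.25)*2 + 0.5*log2(0.5/0.5) = 0.5
  ss <- StateSpace(2, 2, prob = c(0.25, 0.25, 0.5, 0))
  part <- new("StatePartition", blocks = list(c(1L, 2L), 3L),
              seeds = c(1L, 3L), covered = "support")
  expect_equal(conditionalEntropy(ss, part), 0.5)
  # the asymmetric case: P = (0.5, 0.25, 0.25), blocks {1,2},{3}
  ss2 <- StateSpace(2, 2, prob = c(0.5, 0.25, 0.25, 0))
  expect_equal(conditionalEntropy(ss2, part),
               0.5 * log2(0.75 / 0.5) + 0.25 * log2(0.75 / 0.25) + 0.25 * 0)
  # partition missing support states errors
  bad <- new("StatePartition", blocks = list(c(1L, 2L)), seeds = 1L,
             covered = "support")
  expect_error(conditionalEntropy(ss, bad), "cover")
})

test_that("the surrogate equals its decomposition and H at constant relations", {
  set.seed(47)
  for (rep in 1:5) {
    R <- contRelation(c("a", "b", "c")); U <- contRelation(c("s1", "s2"))
    p <- runif(8); p[sample.int(8, 2)] <- 0; p <- p / sum(p)
    ss <- StateSpace(3, 2, prob = p)
    s <- efeSurrogate(ss, R, U)
    expect_equal(s$surrogate, s$viaDecomposition, tolerance = 1e-12)
    expect_equal(s$viaDecomposition, s$H + s$secondTerm)
    expect_lte(s$secondTerm, 1e-12)
    expect_gte(s$secondTerm, -s$H - 1e-12)
    expect_gte(s$surrogate, -1e-12)
  }
  Rc <- constantRelation(c("a", "b", "c")); Uc <- constantRelation(c("s1", "s2"))
  p <- c(0.5, 0.25, 0.125, 0.125, 0, 0, 0, 0)
  sc <- efeSurrogate(StateSpace(3, 2, prob = p), Rc, Uc)
  expect_equal(sc$surrogate, 1.75)
  expect_equal(sc$H, 1.75)
  expect_equal(sc$efe, 3)  # efe still counts the full space
})

test_that("partition blocks are well defined under seed ties", {
  # equal probabilities and tied distances: candidate seeds with equal
  # counting-set size must generate identical blocks
  labs <- c("a", "b")
  v <- diag(2); v[1, 2] <- v[2, 1] <- 0.5
  R <- WeightedRelation(labs, v)
  U <- WeightedRelation(c("s1", "s2"), v)
  ss <- StateSpace(2, 2, prob = rep(0.25, 4))
  prof <- distanceProfile(R, U, ss)
  # symmetric construction gives tied profiles
  expect_true(any(duplicated(prof)))
  part <- statePartition(ss, R, U)
  expect_equal(sort(unlist(partitionBlocks(part))), 1:4)
  expect_equal(anyDuplicated(unlist(partitionBlocks(part))), 0L)
  # states with equal profile always share a block
  for (b in partitionBlocks(part))
    for (d in unique(prof[b]))
      expect_true(all(which(prof == d) %in% b))
})
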