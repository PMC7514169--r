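test_that("completion enumeration covers all assignments and keeps known states", {
  el <- c(node1 = 2L, node2 = 1L, node3 = 3L, node4 = 4L,
          node5 = 1L, node6 = 2L, node7 = 3L, node8 = 4L, node9 = 1L)
  set.seed(3)
  obf <- obfuscate(el, 4L)
  expect_length(obf$hiddenNodes, 4L)
  expect_length(obf$known, 5L)
  cand <- enumerateCompletions(obf, 4L)
  expect_equal(nrow(cand), 256L)
  expect_equal(anyDuplicated(cand), 0L)
  for (nm in names(obf$known))
    expect_true(all(cand[, nm] == obf$known[[nm]]))
  # the hidden columns run over every assignment
  expect_equal(nrow(unique(cand[, obf$hiddenNodes, drop = FALSE])), 256L)
  # k = 0 leaves the element untouched
  obf0 <- obfuscate(el, 0L)
  expect_equal(enumerateCompletions(obf0, 4L)[1, ], el)
  expect_error(obfuscate(el, 10L), "0..n")
  expect_error(obfuscate(unname(el), 2L), "names")
})

test_that("minimum-fe completion recovers a hand-checked argmin and keeps ties", {
  # n = 3, m = 2: R strongly couples node1-node2, weakly node1-node3
  v <- diag(3); v[1, 2] <- v[2, 1] <- 0.9
  v[1, 3] <- v[3, 1] <- 0.1; v[2, 3] <- v[3, 2] <- 0.1
  R <- WeightedRelation(paste0("node", 1:3), v)
  u <- diag(2); u[1, 2] <- u[2, 1] <- 0.1
  U <- WeightedRelation(c("s1", "s2"), u)
  ss <- StateSpace(3, 2)
  obf <- structure(list(known = c(node1 = 1L, node3 = 2L),
                        hiddenNodes = "node2",
                        nodes = paste0("node", 1:3)),
                   class = "ObfuscatedElement")
  # candidates (1,1,2) and (1,2,2); d1 by the oracle decides
  d1 <- oracleD1(v, u, c(1L, 1L, 2L))
  d2 <- oracleD1(v, u, c(1L, 2L, 2L))
  prof <- oracleProfile(v, u, 3, 2)
  res <- minFeComplete(R, U, obf, ss)
  expect_equal(res@candidateCount, 2L)
  expect_equal(nrow(res@completions), 1L)
  want <- if (log2(sum(prof <= d1)) < log2(sum(prof <= d2))) 1L else 2L
  expect_equal(unname(res@completions[1, "node2"]), want)
  expect_equal(want, 1L)  # strong node1-node2 coupling favours same state

  # constant relations make every candidate tie
  resc <- minFeComplete(constantRelation(paste0("node", 1:3)),
                        constantRelation(c("s1", "s2")), obf, ss)
  expect_equal(nrow(resc@completions), 2L)
  expect_equal(resc@minFe, 3)
})

test_that("tie scoring floors the per-observation average but not the mean", {
  truth <- rbind(c(node1 = 1L, node2 = 2L, node3 = 1L))
  # two tied completions getting 3 and 2 hidden nodes right is impossible
  # with 3 hidden nodes unless counts differ; emulate with raw matrices
  comps <- matrix(c(1L, 2L, 1L,   # 3 correct
                    1L, 2L, 2L),  # 2 correct
                  nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, paste0("node", 1:3)))
  res <- new("CompletionResult", completions = comps, minFe = 0,
             candidateCount = 8L, hiddenNodes = paste0("node", 1:3))
  ev <- evaluateCompletions(list(res), truth)
  expect_equal(ev$recorded, 2)          # floor(2.5)
  expect_equal(ev$meanCorrect, 2.5)     # unrounded mean
  expect_equal(ev$meanRecorded, 2)
  expect_equal(ev$ties, 1L)
  expect_equal(unname(ev$proportions), c(0, 0, 1, 0))
  expect_error(evaluateCompletions(list(res, res), truth), "misaligned")
})

test_that("the independent-mode baseline uses per-node training modes", {
  rows <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  T <- toyT(rows, 2)
  f <- independentModeBaseline(T)
  expect_equal(unname(attr(f, "modes")), c(1L, 2L))
  obf <- structure(list(known = c(node2 = 1L), hiddenNodes = "node1",
                        nodes = c("node1", "node2")),
                   class = "ObfuscatedElement")
  out <- f(obf)
  expect_equal(out, c(node1 = 1L, node2 = 1L))
  # modal ties break to the lowest state index
  T2 <- toyT(rbind(c(1L, 1L), c(2L, 2L)), 2)
  expect_equal(unname(attr(independentModeBaseline(T2), "modes")), c(1L, 1L))
})

test_that("guessing distribution and tails match the binomial closed forms", {
  g <- guessingDistribution(4L, 4L)
  expect_equal(g$expectation, 1)
  expect_equal(unname(g$pmf["0"]), (3 / 4)^4)
  expect_equal(unname(g$pmf["4"]), (1 / 4)^4)
  expect_equal(sum(g$pmf), 1)
  expect_equal(unname(g$pmf["1"]), choose(4, 1) * (1 / 4) * (3 / 4)^3)
  expect_equal(guessingDistribution(6L, 4L)$expectation, 1.5)

  t1 <- guessingTail(10L, 0.25, 3L)
  expect_equal(t1$exact, 1 - pbinom(3, 10, 0.25))
  expect_equal(t1$normalApprox,
               pnorm(3, 10 * 0.25, sqrt(10 * 0.25 * 0.75),
                     lower.tail = FALSE))
  # a threshold at or above the maximum has zero exact tail
  expect_equal(guessingTail(10L, 0.25, 10L)$exact, 0)
  expect_error(guessingTail(0L, 0.25, 1L))
  expect_error(guessingDistribution(-1L, 4L))
})

test_that("a full completion experiment on toy data is internally consistent", {
  set.seed(31)
  # strongly coupled 3-node chain: node states mostly equal
  n <- 3; m <- 2
  base <- sample.int(m, 40L, replace = TRUE)
  rows <- cbind(base, base, ifelse(runif(40) < 0.9, base, 3L - base))
  T <- toyT(rows, m)
  fit <- minimiseEfe(T, depth = 5L)
  res <- runCompletionExperiment(fit$R, fit$U, T, T, k = 1L)
  expect_equal(res$minFe$nObservations, 40L)
  expect_equal(res$minFe$k, 1L)
  expect_equal(sum(res$minFe$proportions), 1)
  # perfectly coupled visible nodes let min-fe beat guessing expectation
  expect_gt(res$minFe$meanCorrect, res$guessing$expectation)
  expect_true(res$guessingTailExact >= 0 && res$guessingTailExact <= 1)
})
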