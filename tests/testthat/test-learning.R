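test_that("learned entries land on the dyadic grid and the trace never rises", {
  set.seed(7)
  rows <- matrix(sample.int(3L, 3L * 30L, replace = TRUE), 30L, 3L)
  T <- toyT(rows, 3)
  fit <- minimiseEfe(T, depth = 4L, maxSweeps = 5L)
  # accepted updates land on odd multiples of 2^-depth; entries whose
  # search never improved the objective keep the 0.5 initial value
  grid <- c(seq(1L, 15L, by = 2L) / 16, 0.5)
  offU <- relationMatrix(fit$U)[upper.tri(diag(3))]
  offR <- relationMatrix(fit$R)[upper.tri(diag(3))]
  expect_true(all(c(offU, offR) %in% grid))
  expect_true(all(diff(fit$trace$efe) <= 1e-12))
  expect_lte(fit$efe, fit$initialEfe)
  expect_equal(efeValue(efeEmpirical(fit$R, fit$U, T)), fit$efe)
  expect_error(minimiseEfe(T, depth = 0L), "depth")
})

test_that("tieClasses shares one parameter per displacement class", {
  set.seed(12)
  p <- fieldParams(gridRows = 2L, gridCols = 2L)
  T <- generateTypicalData(50, p, seed = 5)
  fit <- minimiseEfe(T, depth = 3L, maxSweeps = 2L, tieClasses = TRUE)
  cls <- pairDistanceClasses(systemLayout(T))
  rv <- relationMatrix(fit$R)
  byClass <- split(rv[cbind(cls$i, cls$j)], cls$class)
  for (v in byClass) expect_equal(max(v) - min(v), 0)
})

test_that("extendBySymmetry averages classes and fills unseen ones by proximity", {
  lay <- gridLayout(3, 3)
  sub <- c("node2", "node4", "node5", "node6", "node8")  # plus shape
  v <- diag(5)
  dimnames(v) <- list(sub, sub)
  # subset classes: 1 (adjacent to centre), sqrt(2) (arm-arm), 2 (opposite arms)
  sp <- pairDistanceClasses(lay, nodes = sub)
  v[cbind(sp$i, sp$j)] <- ifelse(abs(sp$dist - 1) < 1e-9, 0.9,
                          ifelse(abs(sp$dist - sqrt(2)) < 1e-9, 0.7, 0.5))
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  R <- WeightedRelation(sub, v)
  full <- extendBySymmetry(R, lay)
  fm <- relationMatrix(full)
  expect_equal(dim(fm), c(9L, 9L))
  expect_equal(fm["node1", "node2"], 0.9)   # class 1
  expect_equal(fm["node1", "node5"], 0.7)   # class sqrt(2)
  expect_equal(fm["node1", "node3"], 0.5)   # class 2
  # classes sqrt(5) and 2*sqrt(2) unseen in the subset: nearest observed is 2
  expect_equal(fm["node1", "node6"], 0.5)
  expect_equal(fm["node1", "node9"], 0.5)
  # result is constant on every displacement class
  cls <- pairDistanceClasses(lay)
  for (vv in split(fm[cbind(cls$i, cls$j)], cls$class))
    expect_equal(max(vv) - min(vv), 0)
  expect_error(extendBySymmetry(R, SystemLayout(nodeIds(lay))), "grid")
})

test_that("the bundled reference solution is constant on displacement classes", {
  ex <- greyscaleExample()
  cls <- pairDistanceClasses(ex$layout)
  rv <- relationMatrix(ex$R)
  byClass <- split(rv[cbind(cls$i, cls$j)], cls$class)
  for (v in byClass) expect_equal(max(v) - min(v), 0)
  # the four class values, in decreasing-distance order of decreasing value
  vals <- vapply(split(rv[cbind(cls$i, cls$j)],
                       round(cls$dist, 6)), unique, numeric(1))
  expect_equal(unname(vals[order(as.numeric(names(vals)))]),
               c(0.95313, 0.79688, 0.73438, 0.60938, 0.60938))
  # every entry is within rounding distance (5 decimals) of an odd
  # multiple of 1/64
  off <- rv[upper.tri(rv)]
  grid <- seq(1, 63, by = 2) / 64
  expect_true(all(vapply(off, function(x) min(abs(x - grid)), numeric(1))
                  <= 5.0001e-6))
})

test_that("random relations are valid with roughly uniform off-diagonals", {
  set.seed(19)
  draws <- replicate(500, relationMatrix(randomRelation(letters[1:5])),
                     simplify = FALSE)
  off <- unlist(lapply(draws, function(v) v[upper.tri(v)]))
  expect_true(all(off >= 0 & off <= 1))
  expect_lt(abs(mean(off) - 0.5), 0.02)
  expect_true(all(vapply(draws, function(v) isTRUE(all.equal(v, t(v))),
                         logical(1))))
})

test_that("efe histogram bins, marker percentile and tail length behave", {
  set.seed(23)
  rows <- matrix(sample.int(2L, 2L * 25L, replace = TRUE), 25L, 2L)
  T <- toyT(rows, 2)
  h <- efeHistogram(T, 200L, binWidth = 0.1, marker = 0)
  expect_length(h@samples, 200L)
  expect_equal(sum(h@counts), 200L)
  expect_true(all(h@samples >= 0 & h@samples <= 2 + 1e-9))
  expect_equal(h@markerPercentile, 100 * mean(h@samples <= 0))
  h2 <- efeHistogram(T, 50L, marker = max(h@samples) + 1)
  expect_equal(h2@markerPercentile, 100)

  expect_equal(leftTailLength(c(10, 17, 17.5, 18)), 7.25)
  expect_equal(leftTailLength(h), stats::median(h@samples) - min(h@samples))
  expect_error(leftTailLength(5), "two samples")

  tmp <- tempfile(fileext = ".tsv")
  writeEfeHistogram(h, tmp)
  tab <- utils::read.delim(tmp)
  expect_equal(sum(tab$count), 200L)
  summ <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(summ$marker_percentile, h@markerPercentile)
  unlink(c(tmp, paste0(tmp, ".json")))
})
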