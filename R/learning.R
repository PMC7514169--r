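#' Minimise expected float entropy over the relation pair
#'
#' Coordinate bisection on the free (strict upper-triangular) entries of
#' U and R, minimising the empirical expected float entropy of the
#' typical data. Each entry in turn is re-optimised by a binary search
#' on \[0, 1\]: starting from 1/2, the search at level l compares the
#' two values a distance 2^-l either side of the current value and keeps
#' the better (ties keep the lower), so after `depth` levels the entry
#' lands on an odd multiple of 2^-depth. An entry's new value is
#' accepted only when it does not increase the objective, so the traced
#' efe is non-increasing across sweeps.
#'
#' U entries are updated first (the repertoire relation is
#' lower-dimensional and anchors the induced relations), then R entries
#' in row-major upper-triangular order. With `tieClasses`, R entries
#' sharing a class are updated jointly (parameter sharing), which is how
#' grid symmetry is imposed during learning.
#'
#' @param T a [TypicalData-class].
#' @param depth bisection depth (default 6; learned entries are odd
#'   multiples of 2^-depth).
#' @param maxSweeps maximum number of full passes over the entries
#'   (default 10; the search stops earlier when a sweep yields no
#'   improvement).
#' @param subset optional character vector of node ids: learn on this
#'   node subset only (the standard route for systems above the
#'   state-space cap; see [extendBySymmetry()]).
#' @param tieClasses optional parameter sharing for R: `TRUE` ties node
#'   pairs by their grid displacement class (requires grid coordinates),
#'   or a data.frame with columns `i`, `j`, `class`.
#' @param init initial value of every free entry (default 0.5).
#' @return a list with elements `R` and `U` (the learned
#'   [WeightedRelation-class]s), `efe` (final empirical efe, bpe),
#'   `initialEfe`, `trace` (data.frame of efe per sweep) and `T` (the
#'   typical data actually fitted, after any subsetting).
#' @examples
#' set.seed(1)
#' T <- generateTypicalData(60, fieldParams(gridRows = 2, gridCols = 2))
#' fit <- minimiseEfe(T, depth = 4, maxSweeps = 3)
#' fit$efe <= fit$initialEfe
#' @export
minimiseEfe <- function(T, depth = 6L, maxSweeps = 10L, subset = NULL,
                        tieClasses = NULL, init = 0.5) {
  if (depth < 1L) stop("depth must be >= 1")
  if (!is.null(subset)) T <- subsetNodes(T, subset)
  n <- ncol(stateMatrix(T))
  m <- length(repertoire(T))
  space <- StateSpace(n, m)
  idx <- encodeState(space, stateMatrix(T))
  ids <- nodeIds(systemLayout(T))

  Umat <- matrix(init, m, m); diag(Umat) <- 1
  Rmat <- matrix(init, n, n); diag(Rmat) <- 1
  dimnames(Umat) <- list(repertoire(T), repertoire(T))
  dimnames(Rmat) <- list(ids, ids)

  # parameter groups: each a 2-column index matrix of (i, j) pairs that
  # share one value (mirrored to (j, i))
  groups <- list()
  if (m > 1L)
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m))
      groups[[length(groups) + 1L]] <- list(rel = "U", pr = cbind(i, j))
  rpairs <- if (n > 1L) {
    pp <- which(upper.tri(Rmat), arr.ind = TRUE)
    pp[order(pp[, 1L], pp[, 2L]), , drop = FALSE]
  } else matrix(integer(0), 0, 2)
  if (isTRUE(tieClasses)) tieClasses <- pairDistanceClasses(systemLayout(T))
  if (is.null(tieClasses)) {
    for (r in seq_len(nrow(rpairs)))
      groups[[length(groups) + 1L]] <-
        list(rel = "R", pr = rpairs[r, , drop = FALSE])
  } else {
    key <- paste(ids[rpairs[, 1L]], ids[rpairs[, 2L]])
    tkey <- c(paste(tieClasses$i, tieClasses$j),
              paste(tieClasses$j, tieClasses$i))
    tcls <- rep(as.character(tieClasses$class), 2L)
    cls <- tcls[match(key, tkey)]
    if (anyNA(cls)) stop("tieClasses does not cover every node pair")
    for (cl in unique(cls))
      groups[[length(groups) + 1L]] <-
        list(rel = "R", pr = rpairs[cls == cl, , drop = FALSE])
  }

  objective <- function() {
    prof <- cpp_distance_profile(n, m, Rmat, Umat)
    mean(log2(feCounts(prof, idx)))
  }
  setGroup <- function(g, v) {
    if (g$rel == "U") {
      Umat[g$pr] <<- v; Umat[g$pr[, 2:1, drop = FALSE]] <<- v
    } else {
      Rmat[g$pr] <<- v; Rmat[g$pr[, 2:1, drop = FALSE]] <<- v
    }
  }

  initialEfe <- objective()
  current <- initialEfe
  trace <- data.frame(sweep = 0L, efe = initialEfe)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (g in groups) {
      old <- if (g$rel == "U") Umat[g$pr[1L, 1L], g$pr[1L, 2L]] else
        Rmat[g$pr[1L, 1L], g$pr[1L, 2L]]
      v <- 0.5
      setGroup(g, v); e <- objective()
      for (lev in seq.int(2L, length.out = depth - 1L)) {
        step <- 2^-lev
        setGroup(g, v - step); elo <- objective()
        setGroup(g, v + step); ehi <- objective()
        if (elo <= ehi) { v <- v - step; e <- elo }
        else { v <- v + step; e <- ehi }
      }
      if (e <= current + 1e-12) {
        setGroup(g, v)
        if (e < current - 1e-12) improved <- TRUE
        current <- min(current, e)
      } else {
        setGroup(g, old)
      }
    }
    trace <- rbind(trace, data.frame(sweep = sweep, efe = current))
    if (!improved) break
  }

  list(R = WeightedRelation(ids, Rmat),
       U = WeightedRelation(repertoire(T), Umat),
       efe = current, initialEfe = initialEfe, trace = trace, T = T)
}

#' Extend a subset solution to the full grid by symmetry
#'
#' A node relation learned on a subset of a grid layout is extended to
#' all nodes by assuming the relation depends only on the Euclidean
#' displacement class of the node pair: each class observed among the
#' subset pairs gets the mean of the learned entries in that class, and
#' a class not represented in the subset inherits the value of the
#' observed class with the nearest displacement distance.
#'
#' @param R a [WeightedRelation-class] whose labels are a subset of the
#'   layout's node ids.
#' @param layout a [SystemLayout-class] with grid coordinates covering
#'   all nodes.
#' @return a [WeightedRelation-class] over all nodes of the layout,
#'   constant on displacement classes.
#' @export
extendBySymmetry <- function(R, layout) {
  if (is.null(gridCoords(layout)))
    stop("symmetry extension requires grid coordinates")
  ids <- nodeIds(layout)
  sub <- relationLabels(R)
  if (!all(sub %in% ids)) stop("relation labels must be layout nodes")
  allPairs <- pairDistanceClasses(layout)
  subPairs <- pairDistanceClasses(layout, nodes = sub)
  rv <- relationMatrix(R)
  vals <- rv[cbind(match(subPairs$i, sub), match(subPairs$j, sub))]
  obs <- tapply(vals, subPairs$class, mean)
  obsDist <- tapply(subPairs$dist, subPairs$class, mean)
  full <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(allPairs))) {
    cl <- allPairs$class[r]
    v <- if (cl %in% names(obs)) obs[[cl]] else
      obs[[which.min(abs(obsDist - allPairs$dist[r]))]]
    full[allPairs$i[r], allPairs$j[r]] <- v
    full[allPairs$j[r], allPairs$i[r]] <- v
  }
  WeightedRelation(ids, full)
}

#' Monte-Carlo null histogram of expected float entropy
#'
#' Draws independent uniformly random relation pairs (see
#' [randomRelation()]), computes the empirical efe of the typical data
#' under each, and bins the resulting sample. A candidate solution's efe
#' can be supplied as a marker; its percentile rank among the samples
#' says how isolated the candidate is in the null (solutions of systems
#' with genuine relational structure sit in a long left tail).
#'
#' @param T a [TypicalData-class].
#' @param nSamples number of random relation pairs (several thousand for
#'   a usable histogram).
#' @param binWidth histogram bin interval in bpe (default 0.05).
#' @param marker optional efe value of a candidate solution, bpe.
#' @return an [EfeHistogram-class].
#' @export
efeHistogram <- function(T, nSamples, binWidth = 0.05, marker = NULL) {
  n <- ncol(stateMatrix(T))
  m <- length(repertoire(T))
  space <- StateSpace(n, m)
  idx <- encodeState(space, stateMatrix(T))
  ids <- nodeIds(systemLayout(T))
  samples <- vapply(seq_len(nSamples), function(s) {
    prof <- cpp_distance_profile(n, m, relationMatrix(randomRelation(ids)),
                                 relationMatrix(randomRelation(repertoire(T))))
    mean(log2(feCounts(prof, idx)))
  }, numeric(1))
  lo <- floor(min(samples) / binWidth) * binWidth
  breaks <- seq(lo, max(samples) + binWidth, by = binWidth)
  counts <- as.integer(table(cut(samples, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  new("EfeHistogram", samples = samples, binWidth = binWidth,
      binLeft = breaks[-length(breaks)], counts = counts,
      marker = if (is.null(marker)) numeric(0) else marker,
      markerPercentile = if (is.null(marker)) numeric(0) else
        100 * mean(samples <= marker))
}

setMethod("show", "EfeHistogram", function(object) {
  cat("EfeHistogram:", length(object@samples), "samples, bin",
      object@binWidth, "bpe; range [",
      format(min(object@samples), digits = 5), ",",
      format(max(object@samples), digits = 5), "]\n")
  if (length(object@marker))
    cat("  marker:", format(object@marker, digits = 5), "bpe (percentile",
        format(object@markerPercentile, digits = 3), "%)\n")
})

#' Left-tail length of an efe-histogram
#'
#' Operationalised as median minus minimum of the efe samples: long left
#' tails mark systems whose minimal-efe relations are isolated from the
#' bulk of random relation pairs.
#'
#' @param hist an [EfeHistogram-class] or a numeric vector of efe
#'   samples (at least 2).
#' @return a nonnegative number, bpe.
#' @export
leftTailLength <- function(hist) {
  x <- if (is(hist, "EfeHistogram")) hist@samples else as.numeric(hist)
  if (length(x) < 2L) stop("need at least two samples")
  stats::median(x) - min(x)
}

#' Write an efe-histogram to disk
#'
#' Writes a TSV of (bin_left, count) pairs plus a JSON summary at
#' `<path>.json` with the sample count, bin width, minimum, median,
#' marker and marker percentile.
#'
#' @param hist an [EfeHistogram-class].
#' @param path output TSV path.
#' @export
writeEfeHistogram <- function(hist, path) {
  utils::write.table(data.frame(bin_left = hist@binLeft,
                                count = hist@counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(n_samples = length(hist@samples), bin_width = hist@binWidth,
               min = min(hist@samples), median = stats::median(hist@samples),
               left_tail_length = leftTailLength(hist))
  if (length(hist@marker)) {
    summ$marker <- hist@marker
    summ$marker_percentile <- hist@markerPercentile
  }
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
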