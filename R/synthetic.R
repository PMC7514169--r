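#' Parameters of the synthetic correlated-field generator
#'
#' The generator emulates the statistical structure the method assumes
#' of grid-sampled posterised greyscale image patches: a spatially
#' correlated continuous field, quantised to m shades, sampled at grid
#' locations with fixed spacing. Defaults mirror the canonical
#' experiment: a 3x3 grid with adjacent locations every ten pixels and
#' a four-shade repertoire.
#'
#' @param height,width field size in pixels.
#' @param correlationLength spatial correlation scale in pixels (the
#'   field is white noise smoothed with a Gaussian kernel of standard
#'   deviation correlationLength/2, so the autocorrelation at lag d is
#'   about exp(-(d/correlationLength)^2)); the default 25 puts the
#'   autocorrelation at adjacent sampling locations near 0.85, in line
#'   with the long-range correlation of natural scenes. Values below
#'   0.5 give an unsmoothed white-noise field.
#' @param nShades repertoire size m (>= 2).
#' @param posteriseMode "width" (equal-width intensity bins, the
#'   default — this is what posterising an image does, and it yields
#'   the non-uniform shade frequencies real scenes have) or "quantile"
#'   (equal-frequency shades).
#' @param gridOrigin integer (row, col) of the first sampled pixel.
#' @param gridSpacing pixels between adjacent sampled locations.
#' @param gridRows,gridCols sampling grid dimensions.
#' @return a list of validated parameters.
#' @export
fieldParams <- function(height = 96L, width = 96L, correlationLength = 25,
                        nShades = 4L, posteriseMode = c("width", "quantile"),
                        gridOrigin = c(38L, 38L), gridSpacing = 10L,
                        gridRows = 3L, gridCols = 3L) {
  posteriseMode <- match.arg(posteriseMode)
  if (nShades < 2L) stop("nShades must be >= 2")
  if (correlationLength <= 0) stop("correlationLength must be > 0")
  maxR <- gridOrigin[1L] + gridSpacing * (gridRows - 1L)
  maxC <- gridOrigin[2L] + gridSpacing * (gridCols - 1L)
  if (maxR > height || maxC > width)
    stop("sampling grid does not fit inside the field")
  list(height = as.integer(height), width = as.integer(width),
       correlationLength = correlationLength, nShades = as.integer(nShades),
       posteriseMode = posteriseMode, gridOrigin = as.integer(gridOrigin),
       gridSpacing = as.integer(gridSpacing), gridRows = as.integer(gridRows),
       gridCols = as.integer(gridCols))
}

#' Generate a spatially correlated continuous field
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel
#' (standard deviation correlationLength/2, circular boundary), so the
#' empirical autocorrelation decays on the scale of
#' `correlationLength`. Draws from the current RNG stream.
#'
#' @param params a [fieldParams()] list.
#' @return numeric height x width matrix.
#' @export
generateField <- function(params) {
  noise <- matrix(stats::rnorm(params$height * params$width),
                  params$height, params$width)
  sigma <- params$correlationLength / 2
  if (sigma < 0.25) return(noise)
  # the smoothing filter cannot be longer than the shorter field side
  rad <- min(max(1L, ceiling(3 * sigma)),
             (min(params$height, params$width) - 1L) %/% 2L)
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  sm <- stats::filter(noise, k, circular = TRUE)           # down columns
  sm <- t(stats::filter(t(sm), k, circular = TRUE))        # across rows
  matrix(as.numeric(sm), params$height, params$width)
}

#' Posterise a continuous field to m shades
#'
#' Quantile mode cuts at the empirical m-quantiles so every shade is
#' roughly equally frequent; width mode uses equal-width bins over the
#' field's range. A constant field cannot be quantile-split and falls
#' back to a single shade with a warning.
#'
#' @param field numeric matrix.
#' @param m number of shades.
#' @param mode "quantile" or "width".
#' @return integer matrix of shades in 1..m.
#' @export
posterise <- function(field, m, mode = c("quantile", "width")) {
  mode <- match.arg(mode)
  breaks <- if (mode == "quantile")
    stats::quantile(field, probs = seq(0, 1, length.out = m + 1L),
                    names = FALSE)
  else seq(min(field), max(field), length.out = m + 1L)
  if (anyDuplicated(breaks)) {
    warning("field has too few distinct values; assigning a single shade")
    return(matrix(1L, nrow(field), ncol(field)))
  }
  matrix(as.integer(cut(field, breaks, labels = FALSE,
                        include.lowest = TRUE)),
         nrow(field), ncol(field))
}

#' Sample a posterised image at the grid locations
#'
#' Node (r, c) of the grid takes the shade at pixel
#' (origin + spacing * (r - 1, c - 1)); nodes are ordered row-major.
#'
#' @param image integer matrix of shades.
#' @param params a [fieldParams()] list.
#' @return named integer vector, one state per node.
#' @export
sampleGrid <- function(image, params) {
  rows <- params$gridOrigin[1L] + params$gridSpacing * (seq_len(params$gridRows) - 1L)
  cols <- params$gridOrigin[2L] + params$gridSpacing * (seq_len(params$gridCols) - 1L)
  if (max(rows) > nrow(image) || max(cols) > ncol(image))
    stop("sampling grid lies outside the image")
  out <- as.integer(t(image[rows, cols, drop = FALSE]))
  names(out) <- paste0("node", seq_along(out))
  out
}

#' Generate synthetic typical data
#'
#' Draws one independent correlated field per observation, posterises
#' it, and samples the grid — the synthetic stand-in for obtaining one
#' typical data element per photograph. The repertoire labels are
#' "shade1".."shadem" in increasing brightness order.
#'
#' @param nObs number of observations.
#' @param params a [fieldParams()] list.
#' @param seed optional RNG seed for reproducibility.
#' @return a [TypicalData-class] whose layout carries the grid
#'   coordinates (in grid units).
#' @export
generateTypicalData <- function(nObs, params = fieldParams(), seed = NULL) {
  if (nObs < 1L) stop("nObs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- params$nShades
  states <- matrix(0L, nrow = nObs, ncol = params$gridRows * params$gridCols)
  for (i in seq_len(nObs)) {
    img <- posterise(generateField(params), m, params$posteriseMode)
    states[i, ] <- sampleGrid(img, params)
  }
  lay <- gridLayout(params$gridRows, params$gridCols)
  colnames(states) <- nodeIds(lay)
  TypicalData(states, repertoire = paste0("shade", seq_len(m)), layout = lay)
}

#' Write a posterised field as an ASCII PGM image
#'
#' @param image integer matrix of shades in 1..m.
#' @param path output path.
#' @param maxval maximum grey value written (default m - 1 scaled to
#'   the shade indices).
#' @export
writePGM <- function(image, path, maxval = max(image) - 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(image - 1L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
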