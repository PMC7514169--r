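#' Read an ASCII or binary PGM image
#'
#' Supports the plain (P2) and raw 8-bit (P5) portable graymap formats,
#' returning intensities scaled to \[0, 1\].
#'
#' @param path path to the .pgm file.
#' @return numeric matrix (rows = image rows).
#' @export
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1L]])
    tokens <- tokens[nzchar(tokens)]
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  maxv <- as.integer(tokens[3L])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    if (maxv > 255L) stop("16-bit raw PGM not supported")
    vals <- as.integer(readBin(con, "raw", n = w * h))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

#' Ingest a raster image as a posterised categorical image
#'
#' Reads a PNG or PGM image, desaturates colour images to luminance,
#' optionally enhances contrast, and posterises to m shades. This is
#' the route from real photographs to typical data elements (see
#' [sampleGrid()]); contrast enhancement is optional but can reduce the
#' number of observations needed for the shade structure to emerge.
#'
#' @param path image path (.png, .pgm).
#' @param m number of shades.
#' @param contrast "none", "stretch" (min-max) or "equalize" (histogram
#'   equalisation).
#' @param mode posterisation mode, see [posterise()].
#' @return integer matrix of shades in 1..m.
#' @export
ingestImage <- function(path, m, contrast = c("none", "stretch", "equalize"),
                        mode = "quantile") {
  contrast <- match.arg(contrast)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    gray <- if (length(dim(img)) == 3L)
      0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    gray <- readPGM(path)
  } else stop("unsupported image format: ", path)
  if (contrast == "stretch") {
    rng <- range(gray)
    if (diff(rng) > 0) gray <- (gray - rng[1L]) / diff(rng)
  } else if (contrast == "equalize") {
    gray <- matrix(stats::ecdf(gray)(gray), nrow(gray), ncol(gray))
  }
  posterise(gray, m, mode)
}
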