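#' Bundled reference system: nine greyscale nodes, four shades
#'
#' A worked example of the canonical system: a 3x3 pixel-sampling grid
#' with a four-shade repertoire, one recorded observation, and an
#' approximate minimal-efe relation pair for it (learned on a five-node
#' subset of natural-scene photograph data and extended to all nine
#' nodes by grid symmetry). The shade labels are the numeric intensity
#' labels of the original greyscale and are treated as opaque strings.
#'
#' All entries of the relation pair are (within printing precision)
#' odd multiples of 2^-6, the footprint of a depth-6 bisection, and the
#' node relation is constant on grid displacement classes.
#'
#' @return a list: `layout` (3x3 [SystemLayout-class]), `repertoire`
#'   (four shade labels), `element` (named integer state vector of the
#'   recorded observation), `U` and `R`
#'   ([WeightedRelation-class]s).
#' @examples
#' ex <- greyscaleExample()
#' relationMatrix(ex$U)["0.000", "294.449"]  # 0.04688
#' @export
greyscaleExample <- function() {
  shades <- c("0.000", "147.224", "294.449", "441.673")
  layout <- gridLayout(3L, 3L)
  element <- c(1L, 3L, 3L, 1L, 2L, 3L, 2L, 1L, 2L)
  names(element) <- nodeIds(layout)
  U <- matrix(c(
    1,       0.29688, 0.04688, 0.01563,
    0.29688, 1,       0.42188, 0.10938,
    0.04688, 0.42188, 1,       0.32813,
    0.01563, 0.10938, 0.32813, 1), 4L, 4L, byrow = TRUE)
  R <- matrix(c(
    1,       0.95313, 0.73438, 0.95313, 0.79688, 0.60938, 0.73438, 0.60938, 0.60938,
    0.95313, 1,       0.95313, 0.79688, 0.95313, 0.79688, 0.60938, 0.73438, 0.60938,
    0.73438, 0.95313, 1,       0.60938, 0.79688, 0.95313, 0.60938, 0.60938, 0.73438,
    0.95313, 0.79688, 0.60938, 1,       0.95313, 0.73438, 0.95313, 0.79688, 0.60938,
    0.79688, 0.95313, 0.79688, 0.95313, 1,       0.95313, 0.79688, 0.95313, 0.79688,
    0.60938, 0.79688, 0.95313, 0.73438, 0.95313, 1,       0.60938, 0.79688, 0.95313,
    0.73438, 0.60938, 0.60938, 0.95313, 0.79688, 0.60938, 1,       0.95313, 0.73438,
    0.60938, 0.73438, 0.60938, 0.79688, 0.95313, 0.79688, 0.95313, 1,       0.95313,
    0.60938, 0.60938, 0.73438, 0.60938, 0.79688, 0.95313, 0.73438, 0.95313, 1),
    9L, 9L, byrow = TRUE)
  list(layout = layout, repertoire = shades, element = element,
       U = WeightedRelation(shades, U),
       R = WeightedRelation(nodeIds(layout), R))
}
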