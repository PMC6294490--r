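#' Construct a locus layout
#'
#' @param origin_pos replication origin position (bp), upstream of array 1.
#' @param array1_pos,array2_pos operator-array insertion coordinates (bp);
#'   array 1 (lacO, green) extends away from the interval on the origin side,
#'   array 2 (tetO, red) away on the distal side, so
#'   \code{array2_pos - array1_pos} is the inner edge-to-edge spacing.
#' @param array_len operator array length (kb).
#' @param obstacle_pos optional obstacle (G-quadruplex) coordinate (bp),
#'   strictly between the arrays.
#' @param obstacle_strand \code{"lagging"} or \code{"leading"}.
#' @return a [LocusLayout-class].
#' @examples
#' locusLayout(320000, 332960, 352960, array_len = 10)
#' @export
locusLayout <- function(origin_pos, array1_pos, array2_pos, array_len,
                        obstacle_pos = NA_real_,
                        obstacle_strand = NA_character_) {
  new("LocusLayout", origin_pos = as.numeric(origin_pos),
      array1_pos = as.numeric(array1_pos),
      array2_pos = as.numeric(array2_pos),
      array_len = as.numeric(array_len),
      obstacle_pos = as.numeric(obstacle_pos),
      obstacle_strand = as.character(obstacle_strand))
}

#' Reference locus layouts
#'
#' `nominalLocusLayout()` uses the schematic construction: 10 kb operator
#' arrays whose inner edges are 20 kb apart, so the mid-array to mid-array
#' distance — the interval whose replication time the assay reports — is
#' 30 kb. `chrIVLocusLayout()` uses the strain coordinates on chromosome IV
#' (lacO inserted at 332,960, tetO at 352,560, the G4 motif at 344,119): the
#' inner spacing is then 19.6 kb and, with 11 kb arrays, the expected
#' mid-array distance is 30.6 kb.
#'
#' @param obstacle include the G4 obstacle at chrIV:344,119?
#' @param obstacle_strand strand carrying the G4 motif.
#' @return a [LocusLayout-class].
#' @examples
#' locusGeometry(nominalLocusLayout())$mid_to_mid_kb       # 30
#' locusGeometry(chrIVLocusLayout())$obstacle_to_array2_kb # 8.4
#' @export
nominalLocusLayout <- function(obstacle = TRUE, obstacle_strand = "lagging") {
  locusLayout(origin_pos = 320000, array1_pos = 332960, array2_pos = 352960,
              array_len = 10,
              obstacle_pos = if (obstacle) 344119 else NA_real_,
              obstacle_strand = if (obstacle) obstacle_strand else NA_character_)
}

#' @rdname nominalLocusLayout
#' @export
chrIVLocusLayout <- function(obstacle = TRUE, obstacle_strand = "lagging") {
  locusLayout(origin_pos = 320000, array1_pos = 332960, array2_pos = 352560,
              array_len = 11,
              obstacle_pos = if (obstacle) 344119 else NA_real_,
              obstacle_strand = if (obstacle) obstacle_strand else NA_character_)
}

# distances displayed to 0.1 kb, truncated toward zero (8.441 -> 8.4)
kbDisplay <- function(x) trunc(round(x * 10, 6)) / 10

#' Inter-point distances of a locus layout
#'
#' The mid-array to mid-array distance is the inner spacing plus two half
#' arrays (the midpoint of each array lies array_len/2 outside its inner
#' edge). Distances are reported to 0.1 kb, truncated toward zero, with the
#' exact values retained in \code{attr(, "exact")}.
#'
#' @param layout a [LocusLayout-class].
#' @return named list with \code{mid_to_mid_kb} and, when an obstacle is
#'   present, \code{array1_to_obstacle_kb} and \code{obstacle_to_array2_kb}.
#' @examples
#' locusGeometry(nominalLocusLayout())
#' @export
locusGeometry <- function(layout) {
  stopifnot(is(layout, "LocusLayout"))
  validObject(layout)
  spacing <- (layout@array2_pos - layout@array1_pos) / 1000
  exact <- list(mid_to_mid_kb = spacing + layout@array_len)
  if (!is.na(layout@obstacle_pos)) {
    exact$array1_to_obstacle_kb <- (layout@obstacle_pos - layout@array1_pos) / 1000
    exact$obstacle_to_array2_kb <- (layout@array2_pos - layout@obstacle_pos) / 1000
  }
  out <- lapply(exact, kbDisplay)
  attr(out, "exact") <- exact
  out
}
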