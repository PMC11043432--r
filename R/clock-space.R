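#' Clock-space geometry
#'
#' The imagined environment is a clock face: the integers 1--12 sit on the
#' vertices of a regular dodecagon, 12 at the top, numbers increasing
#' clockwise. Direction angles follow the mathematical convention
#' (degrees counterclockwise from east), under which every chord between
#' two clock numbers has a direction that is a multiple of 15 degrees.
#'
#' @param radius Circle radius in arbitrary units (default 1).
#' @return An object of class `clock_space`.
#' @export
clock_space <- function(radius = 1) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(
    list(n_positions = 12L, radius = radius,
         convention = "12 at top, clockwise numbering, angles CCW from east"),
    class = "clock_space")
}

#' @export
print.clock_space <- function(x, ...) {
  cat("<clock_space> 12 positions, radius", x$radius, "\n")
  invisible(x)
}

#' Planar coordinates of a clock number
#'
#' Position `n` lies at angle `(90 - 30*(n mod 12)) mod 360` degrees on the
#' circle, so 12 is at the top and 3 due east.
#'
#' @param n Integer vector of clock numbers in 1..12.
#' @param space A [clock_space()].
#' @return A matrix with columns `x`, `y` (one row per element of `n`).
#' @export
number_position <- function(n, space = clock_space()) {
  if (any(n < 1 | n > 12 | n != round(n))) {
    stop("clock numbers must be integers in 1..12")
  }
  ang <- (90 - 30 * (n %% 12)) %% 360
  cbind(x = space$radius * cospi(ang / 180),
        y = space$radius * sinpi(ang / 180))
}

#' Circular distance between two clock numbers
#'
#' The number of 30-degree steps separating `a` and `b` along the shorter
#' arc, an integer in 1..6 (e.g. from 9 to 12 the distance is 3).
#'
#' @param a,b Clock numbers in 1..12 (vectorised; `a != b` elementwise).
#' @return Integer vector of circular distances.
#' @export
circular_distance <- function(a, b) {
  if (any(a == b)) stop("circular distance undefined for a == b")
  d <- abs(a - b)
  as.integer(pmin(d, 12 - d))
}

#' Movement direction of a clock path
#'
#' Direction of the vector from position `a` to position `b`, in degrees
#' counterclockwise from east, in \[0, 360). Always a multiple of 15 for
#' dodecagon vertices.
#'
#' @inheritParams circular_distance
#' @param space A [clock_space()].
#' @return Numeric vector of directions in degrees.
#' @export
path_direction <- function(a, b, space = clock_space()) {
  if (any(a == b)) stop("path direction undefined for a == b")
  pa <- number_position(a, space)
  pb <- number_position(b, space)
  d <- (atan2(pb[, "y"] - pa[, "y"], pb[, "x"] - pa[, "x"]) * 180 / pi) %% 360
  # chord directions are exact multiples of 15; snap away float fuzz
  unname(round(d / 15) %% 24 * 15)
}

#' Left/right judgment for a target number
#'
#' The behavioural question at the end of each trial: standing at the end
#' point having walked `start -> end`, is the `target` number to the left
#' or to the right?  Decided by the sign of the planar cross product
#' between the movement vector and the vector from the end position to the
#' target position: positive -> left, negative -> right.
#'
#' @param start,end Clock numbers defining the path.
#' @param target Clock number, not equal to start or end.
#' @param space A [clock_space()].
#' @param tol Collinearity tolerance on the cross product, scaled by
#'   `radius^2`; a target on the heading line is an invalid design.
#' @return `"left"` or `"right"` (vectorised).
#' @export
judge_side <- function(start, end, target, space = clock_space(),
                       tol = 1e-9) {
  if (any(target == start | target == end)) {
    stop("target must differ from start and end")
  }
  ps <- number_position(start, space)
  pe <- number_position(end, space)
  pt <- number_position(target, space)
  v <- pe - ps
  w <- pt - pe
  cr <- v[, "x"] * w[, "y"] - v[, "y"] * w[, "x"]
  if (any(abs(cr) < tol * space$radius^2)) {
    stop("target collinear with the movement direction: invalid design")
  }
  unname(ifelse(cr > 0, "left", "right"))
}

#' Enumerate the valid experimental paths
#'
#' All unordered pairs of clock numbers whose circular distance is 3, 4 or
#' 5: repeated paths, paths between adjacent numbers, diameters (which
#' cross the centre) and distance-2 chords are excluded, leaving 36 unique
#' paths in three length classes (short = 3, medium = 4, long = 5).
#'
#' @param space A [clock_space()].
#' @return A data frame with columns `start`, `end` (`start < end`),
#'   `circ_dist` and `length_class`.
#' @export
enumerate_valid_paths <- function(space = clock_space()) {
  g <- expand.grid(start = 1:12, end = 1:12)
  g <- g[g$start < g$end, ]
  g$circ_dist <- circular_distance(g$start, g$end)
  g <- g[g$circ_dist %in% 3:5, ]
  g$length_class <- c("short", "medium", "long")[g$circ_dist - 2L]
  rownames(g) <- NULL
  g
}

#' All 72 directed paths
#'
#' The directed closure of [enumerate_valid_paths()]: both traversal
#' directions of each valid chord, with direction angle and length class.
#'
#' @param space A [clock_space()].
#' @return A data frame with columns `start`, `end`, `direction_deg`,
#'   `circ_dist`, `length_class`.
#' @export
directed_paths <- function(space = clock_space()) {
  u <- enumerate_valid_paths(space)
  d <- rbind(u, data.frame(start = u$end, end = u$start,
                           circ_dist = u$circ_dist,
                           length_class = u$length_class))
  d$direction_deg <- path_direction(d$start, d$end, space)
  rownames(d) <- NULL
  d[, c("start", "end", "direction_deg", "circ_dist", "length_class")]
}

#' Admissible target numbers for a directed path
#'
#' Targets must differ from the start and end numbers and must not be
#' circularly adjacent to the end number.
#'
#' @keywords internal
admissible_targets <- function(start, end, space = clock_space()) {
  excl <- c(start, end, (end %% 12) + 1L, ((end - 2L) %% 12) + 1L)
  setdiff(1:12, excl)
}
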