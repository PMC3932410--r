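# Planar geometry helpers shared across the package.
#
# Coordinate convention: degrees of visual angle, origin at the stimulus
# center, x rightward, y upward. Orientation theta is in degrees, in
# [0, 180), with 0 = vertical and positive values clockwise (the convention
# of the low-level orientation task, which uses a vertical reference).

#' Orientation of a line segment
#'
#' @param x0,y0,x1,y1 Segment endpoint coordinates (vectors, degrees).
#' @return Orientations in degrees, in `[0, 180)`; 0 is vertical, positive
#'   clockwise.
#' @examples
#' segment_orientation(0, 0, 0, 1)  # vertical -> 0
#' segment_orientation(0, 0, 1, 0)  # horizontal -> 90
#' @export
segment_orientation <- function(x0, y0, x1, y1) {
  (atan2(x1 - x0, y1 - y0) * 180 / pi) %% 180
}

#' Circular orientation difference folded to at most 90 degrees
#'
#' Orientations are axial (theta and theta + 180 are the same grating), so
#' differences are reduced modulo 180 and folded into `[0, 90]`.
#'
#' @param a,b Orientations in degrees.
#' @return Absolute folded differences in `[0, 90]`.
#' @export
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Distance from points to line segments
#'
#' Vectorised closed-form Euclidean distance from each point to the nearest
#' location on the corresponding segment (arguments recycle).
#'
#' @param px,py Point coordinates.
#' @param x0,y0,x1,y1 Segment endpoints.
#' @return Distances (degrees).
#' @export
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0
  vy <- y1 - y0
  wx <- px - x0
  wy <- py - y0
  l2 <- vx * vx + vy * vy
  t <- pmax(0, pmin(1, (wx * vx + wy * vy) / l2))
  dx <- wx - t * vx
  dy <- wy - t * vy
  sqrt(dx * dx + dy * dy)
}

# For each point, index of the nearest segment in a frame table and the
# distance to it. `frame` is a data.frame with x0, y0, x1, y1. Ties break by
# the lowest row index after ordering segments by label (the frame tables are
# stored label-sorted), giving deterministic assignment.
nearest_segment <- function(px, py, frame) {
  n <- length(px)
  s <- nrow(frame)
  d <- point_segment_distance(rep(px, each = s), rep(py, each = s),
                              rep(frame$x0, n), rep(frame$y0, n),
                              rep(frame$x1, n), rep(frame$y1, n))
  dm <- matrix(d, nrow = s, ncol = n)
  idx <- max.col(-t(dm), ties.method = "first")
  list(index = idx, distance = dm[cbind(idx, seq_len(n))])
}

# Mirror orientation across the vertical meridian: theta -> (180 - theta) mod 180.
mirror_orientation <- function(theta) (180 - theta) %% 180
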