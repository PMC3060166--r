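#' Normalize an angle to the interval (-pi, pi]
#'
#' All compass angles in the package live in a fixed external ("world")
#' reference frame: angle 0 points along +x ("east") and angles increase
#' counter-clockwise.
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(3 * pi)   # pi
#' wrap_angle(-pi)      # pi
wrap_angle <- function(theta) {
  r <- theta %% (2 * pi)
  ifelse(r > pi, r - 2 * pi, r)
}

#' Polar vector in the world compass frame
#'
#' The universal currency between the procedural memories and the motor
#' stage: a direction (compass angle, radians) plus a non-negative length.
#' Lengths are in spatial length units for displacement-like vectors and
#' dimensionless for salience-weighted outputs.
#'
#' @param angle compass angle in radians; normalized to (-pi, pi].
#' @param length non-negative scalar.
#' @return an object of class `polar_vector` with fields `angle`, `length`.
#' @export
#' @examples
#' polar_vector(pi / 4, 10)
polar_vector <- function(angle = 0, length = 0) {
  stopifnot(is.numeric(angle), is.numeric(length),
            length(angle) == 1L, length(length) == 1L,
            is.finite(angle), is.finite(length))
  if (length < 0) stop("polar_vector length must be non-negative")
  structure(list(angle = wrap_angle(angle), length = length),
            class = "polar_vector")
}

#' @export
print.polar_vector <- function(x, ...) {
  cat(sprintf("<polar_vector angle = %.4f rad, length = %.4f>\n",
              x$angle, x$length))
  invisible(x)
}

#' Convert a polar vector to Cartesian components
#'
#' @param p a [polar_vector()].
#' @return numeric `c(x, y)`.
#' @export
pv_xy <- function(p) {
  stopifnot(inherits(p, "polar_vector"))
  c(x = p$length * cos(p$angle), y = p$length * sin(p$angle))
}

#' Build a polar vector from Cartesian components
#'
#' A zero displacement maps to angle 0, length 0 by convention; callers
#' must treat lengths below their own epsilon as "no direction".
#'
#' @param x,y Cartesian components (length units).
#' @return a [polar_vector()].
#' @export
pv_from_xy <- function(x, y) {
  len <- sqrt(x^2 + y^2)
  if (len < 1e-15) return(polar_vector(0, 0))
  polar_vector(atan2(y, x), len)
}

#' Add two polar vectors
#'
#' @param a,b [polar_vector()] objects.
#' @return their vector sum as a [polar_vector()].
#' @export
pv_add <- function(a, b) {
  xa <- pv_xy(a); xb <- pv_xy(b)
  pv_from_xy(xa[[1]] + xb[[1]], xa[[2]] + xb[[2]])
}

#' Subtract two polar vectors
#'
#' @param a,b [polar_vector()] objects.
#' @return `a - b` as a [polar_vector()].
#' @export
pv_sub <- function(a, b) {
  xa <- pv_xy(a); xb <- pv_xy(b)
  pv_from_xy(xa[[1]] - xb[[1]], xa[[2]] - xb[[2]])
}

#' Weighted sum of unit vectors
#'
#' The motor output stage: every procedure proposes a direction, its
#' post-inhibition salience acts as the weight, and the proposals are summed
#' as vectors. The angle of the resultant is the commanded walking
#' direction. An empty input or fully cancelling weights yield the zero
#' vector (angle reported as 0 by convention).
#'
#' @param angles numeric vector of compass angles (radians).
#' @param weights numeric vector of non-negative weights, recycled against
#'   `angles` is not allowed: lengths must match.
#' @return a [polar_vector()]: the resultant of `weights * unit(angles)`.
#' @export
#' @examples
#' weighted_vector_sum(c(0, pi / 2), c(0.12, 0.12))  # angle pi/4
weighted_vector_sum <- function(angles, weights) {
  stopifnot(is.numeric(angles), is.numeric(weights),
            length(angles) == length(weights))
  if (length(angles) == 0L) return(polar_vector(0, 0))
  if (any(!is.finite(angles)) || any(!is.finite(weights)))
    stop("angles and weights must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  pv_from_xy(sum(weights * cos(angles)), sum(weights * sin(angles)))
}

#' Compass bearing from one position to another
#'
#' Positions are plain numeric `c(x, y)` pairs in world coordinates.
#'
#' @param p,q numeric positions `c(x, y)`, with `p != q`.
#' @return compass angle of `q - p` in radians.
#' @export
#' @examples
#' angle_between(c(1, 1), c(2, 2))  # pi/4
angle_between <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 2L, length(q) == 2L,
            all(is.finite(p)), all(is.finite(q)))
  d <- q - p
  if (all(d == 0))
    stop(structure(
      class = c("antnav_degenerate_direction", "error", "condition"),
      list(message = "degenerate direction: positions coincide",
           call = sys.call(-1))))
  atan2(d[[2]], d[[1]])
}

#' Euclidean distance between two positions
#'
#' @param p,q numeric positions `c(x, y)`.
#' @return distance in length units.
#' @export
dist_xy <- function(p, q) {
  sqrt(sum((q - p)^2))
}
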