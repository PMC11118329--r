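#' Vectorized even-odd point-in-polygon test
#'
#' Ray-casting membership test for planar polygons. Points exactly on an
#' edge follow the even-odd crossing convention; chamber polygons are kept
#' disjoint so continuous coordinates are unambiguous in practice.
#'
#' @param px,py point coordinates.
#' @param poly vertex matrix [n x 2] (implicitly closed).
#' @param strict if TRUE, points lying on the polygon boundary are not
#'   counted (strict interior membership).
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, poly, strict = FALSE) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  if (strict)
    inside <- inside & distanceToBoundary(px, py, poly) > 1e-9
  inside
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each point to the polygon's edges
#' (regardless of whether the point is inside).
#'
#' @param px,py point coordinates.
#' @param poly vertex matrix [n x 2].
#' @return numeric vector of distances (cm).
#' @export
distanceToBoundary <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Frame indices whose timestamps fall in the half-open span [t0, t1).
# Frame i covers time (i - 1) / fps.
spanFrames <- function(span, fps, nframes) {
  t <- (seq_len(nframes) - 1) / fps
  which(t >= span[1] & t < span[2])
}

frameTimes <- function(nframes, fps) (seq_len(nframes) - 1) / fps

# Total overlap of intervals [on, off] with the span [s0, s1).
intervalOverlap <- function(onset, offset, span) {
  if (!length(onset)) return(0)
  sum(pmax(0, pmin(offset, span[2]) - pmax(onset, span[1])))
}

# Deterministic per-session seed derivation from a master seed (splittable
# counter scheme; stays below 2^31).
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 1000003) * 2011 + index * 7919) %%
    2147483647L
}

wrapAngle <- function(a) atan2(sin(a), cos(a))
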