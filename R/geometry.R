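# Polygon primitives shared by the detection pipeline and strata geometry.
# Polygons are n x 2 matrices (columns x, y) of >= 3 vertices, implicitly
# closed, in 0-based image coordinates.

.as_polygon <- function(region) {
  p <- as.matrix(region)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop("a region must be an n x 2 matrix of at least 3 vertices")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

# signed area (shoelace); positive when vertices wind counterclockwise in a
# y-up frame (clockwise on screen with y pointing down)
.polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area
#' @param region an n x 2 vertex matrix (implicitly closed).
#' @return Absolute area in squared pixels.
#' @export
polygon_area <- function(region) abs(.polygon_signed_area(.as_polygon(region)))

# do segments (p1,p2) and (p3,p4) properly intersect (interiors cross)?
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.polygon_is_simple <- function(p) {
  n <- nrow(p)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (.segments_cross(p[i, ], p[idx(i + 1L), ], p[j, ], p[idx(j + 1L), ]))
        return(FALSE)
    }
  }
  TRUE
}

.validate_region <- function(region) {
  p <- .as_polygon(region)
  if (!.polygon_is_simple(p)) stop("analysis region must be a simple polygon")
  if (polygon_area(p) <= 0) stop("analysis region must have positive area")
  p
}

# squared distance from point q to segment (a, b)
.point_segment_dist2 <- function(qx, qy, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((qx - ax) * vx + (qy - ay) * vy) / pmax(len2, 1e-300)))
  t[len2 == 0] <- 0
  (ax + t * vx - qx)^2 + (ay + t * vy - qy)^2
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' @param px,py point coordinate vectors.
#' @param region an n x 2 vertex matrix (implicitly closed).
#' @param tol points within \code{tol} of an edge count as inside.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, region, tol = 1e-9) {
  p <- .as_polygon(region)
  n <- nrow(p)
  xs <- p[, 1]; ys <- p[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  vapply(seq_along(px), function(i) {
    qx <- px[i]; qy <- py[i]
    d2 <- .point_segment_dist2(qx, qy, xs, ys, xe, ye)
    if (any(d2 <= tol^2)) return(TRUE)
    # even-odd ray casting toward +x
    cross <- (ys > qy) != (ye > qy)
    if (!any(cross)) return(FALSE)
    xint <- xs[cross] + (qy - ys[cross]) / (ye[cross] - ys[cross]) *
      (xe[cross] - xs[cross])
    sum(xint > qx) %% 2L == 1L
  }, logical(1))
}
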