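# Partition of the analysis region into basal / medial / superior epithelial
# strata from the region contour and a user-marked basal point.

#' Minimum-area enclosing rectangle
#'
#' Computes the minimum-area rotated rectangle enclosing the region vertices
#' by scanning the convex-hull edge orientations (rotating calipers: the
#' optimal rectangle has one side collinear with a hull edge). Corners are
#' returned in cyclic order with positive shoelace orientation (in image
#' coordinates, y down), starting from the corner nearest the first region
#' vertex.
#'
#' @param region an n x 2 vertex matrix.
#' @return A 4 x 2 matrix of corners (rows A, B, C, D; sides AB, BC, CD, DA).
#' @export
min_area_rect <- function(region) {
  p <- .as_polygon(region)
  hull_idx <- grDevices::chull(p[, 1], p[, 2])
  hull <- p[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3L || polygon_area(hull) <= 0)
    stop("degenerate region: vertices are collinear")
  n <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[(i %% n) + 1L, ]
    u <- b - a
    len <- sqrt(sum(u^2))
    if (len == 0) next
    u <- u / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best_area - 1e-12) {
      best_area <- area
      best <- list(u = u, v = v, u0 = min(pu), u1 = max(pu),
                   v0 = min(pv), v1 = max(pv))
    }
  }
  corners_uv <- rbind(c(best$u0, best$v0), c(best$u1, best$v0),
                      c(best$u1, best$v1), c(best$u0, best$v1))
  corners <- corners_uv[, 1] %o% best$u + corners_uv[, 2] %o% best$v
  if (.polygon_signed_area(corners) < 0) corners <- corners[c(1, 4, 3, 2), ]
  d2 <- (corners[, 1] - p[1, 1])^2 + (corners[, 2] - p[1, 2])^2
  start <- which.min(d2)
  corners <- corners[((start - 1L + 0:3) %% 4L) + 1L, , drop = FALSE]
  colnames(corners) <- c("x", "y")
  rownames(corners) <- c("A", "B", "C", "D")
  corners
}

#' Rectangle side closest to a point
#'
#' @param rect a 4 x 2 corner matrix from \code{\link{min_area_rect}}.
#' @param p a point \code{c(x, y)}.
#' @return 0-based side index: AB = 0, BC = 1, CD = 2, DA = 3 (ties go to the
#'   lowest index).
#' @export
closest_rect_side <- function(rect, p) {
  a <- rect; b <- rect[c(2, 3, 4, 1), , drop = FALSE]
  d2 <- .point_segment_dist2(p[1], p[2], a[, 1], a[, 2], b[, 1], b[, 2])
  unname(which.min(d2)) - 1L
}

# intersection parameters t of the line S + t*w with the polygon boundary
.line_polygon_hits <- function(S, w, poly, tol) {
  n <- nrow(poly)
  q1 <- poly
  q2 <- poly[c(seq_len(n)[-1], 1L), , drop = FALSE]
  e <- q2 - q1
  ts <- numeric(0)
  for (k in seq_len(n)) {
    d <- e[k, 1] * w[2] - e[k, 2] * w[1]
    if (abs(d) < 1e-12) next                  # parallel edge
    dx <- S[1] - q1[k, 1]; dy <- S[2] - q1[k, 2]
    s <- (dx * w[2] - dy * w[1]) / d          # parameter along the edge
    if (s < -1e-9 || s >= 1 - 1e-9) next      # half-open to avoid vertex doubles
    t <- if (abs(w[1]) >= abs(w[2]))
      (q1[k, 1] + s * e[k, 1] - S[1]) / w[1]
    else
      (q1[k, 2] + s * e[k, 2] - S[2]) / w[2]
    ts <- c(ts, t)
  }
  ts <- sort(ts)
  if (length(ts) > 1L) ts <- ts[c(TRUE, diff(ts) > tol)]  # dedupe vertex hits
  ts
}

#' Partition the analysis region into basal, medial and superior strata
#'
#' Implements the strata construction: the minimum enclosing rectangle of the
#' region is computed and the rectangle side closest to the basal point is
#' taken as the basal side. \code{n_lines} sweep lines perpendicular to the
#' basal side (parallel to its adjacent sides) are placed at evenly spaced
#' stations along it; each line crosses the region contour in two points
#' (\code{pc1} nearest the basal side, \code{pc2} opposite) and the chord
#' between them is divided at 1/3 and 2/3 of its Euclidean length. Chaining
#' the contour crossings and the division points across the sweep yields the
#' three stratum polygons. Sweep lines that cross the contour in a number of
#' points other than two (non-convex folds) are skipped; if more than 20% of
#' lines are skipped the region is rejected as not epithelium-like, so the
#' user can re-draw the ROI.
#'
#' @param region an n x 2 vertex matrix (simple, positive area).
#' @param basal_point \code{c(x, y)}, strictly outside the region, marking
#'   the basal side.
#' @param n_lines number of sweep lines (default 100; >= 2).
#' @return An object of class \code{strata_partition}: list with polygons
#'   \code{basal}, \code{medial}, \code{superior}, the number of lines used
#'   and skipped.
#' @export
partition_layers <- function(region, basal_point, n_lines = 100L) {
  p <- .validate_region(region)
  stopifnot(n_lines >= 2L)
  if (point_in_polygon(basal_point[1], basal_point[2], p))
    stop("basal point must lie outside the analysis region")
  rect <- min_area_rect(p)
  sb <- closest_rect_side(rect, basal_point)
  a <- rect[sb + 1L, ]
  b <- rect[(sb + 1L) %% 4L + 1L, ]
  len <- sqrt(sum((b - a)^2))
  u <- (b - a) / len
  # inward perpendicular: toward the rectangle centre
  ctr <- colMeans(rect)
  w <- c(-u[2], u[1])
  if (sum((ctr - a) * w) < 0) w <- -w
  eps <- len / (10 * n_lines)
  stations <- eps + (seq_len(n_lines) - 1L) * (len - 2 * eps) / (n_lines - 1L)
  tol <- 1e-7 * max(len, 1)
  pc1 <- pc2 <- p1 <- p2 <- matrix(NA_real_, n_lines, 2L)
  ok <- logical(n_lines)
  for (i in seq_len(n_lines)) {
    S <- a + stations[i] * u
    ts <- .line_polygon_hits(S, w, p, tol)
    if (length(ts) != 2L) next
    ok[i] <- TRUE
    q1 <- S + ts[1] * w; q2 <- S + ts[2] * w   # ts sorted: q1 nearest basal
    pc1[i, ] <- q1; pc2[i, ] <- q2
    p1[i, ] <- q1 + (q2 - q1) / 3
    p2[i, ] <- q1 + 2 * (q2 - q1) / 3
  }
  n_ok <- sum(ok)
  if (n_ok < 0.8 * n_lines)
    stop("region is not epithelium-like: ", n_lines - n_ok, " of ", n_lines,
         " sweep lines crossed the contour in a number of points other than 2; ",
         "re-draw the ROI")
  if (n_ok < 2L) stop("too few usable sweep lines")
  kp <- which(ok)
  rev_kp <- rev(kp)
  part <- structure(list(
    basal = rbind(pc1[kp, , drop = FALSE], p1[rev_kp, , drop = FALSE]),
    medial = rbind(p1[kp, , drop = FALSE], p2[rev_kp, , drop = FALSE]),
    superior = rbind(p2[kp, , drop = FALSE], pc2[rev_kp, , drop = FALSE]),
    n_lines = as.integer(n_lines), n_skipped = as.integer(n_lines - n_ok)),
    class = "strata_partition")
  part
}

#' @export
print.strata_partition <- function(x, ...) {
  cat(sprintf("<strata_partition> %d sweep lines (%d skipped); areas b/m/s = %.1f / %.1f / %.1f px^2\n",
              x$n_lines, x$n_skipped, polygon_area(x$basal),
              polygon_area(x$medial), polygon_area(x$superior)))
  invisible(x)
}

.min_boundary_dist2 <- function(qx, qy, poly) {
  n <- nrow(poly)
  b <- poly[c(seq_len(n)[-1], 1L), , drop = FALSE]
  min(.point_segment_dist2(qx, qy, poly[, 1], poly[, 2], b[, 1], b[, 2]))
}

#' Assign cells to epithelial strata
#'
#' Containment is tested against the basal, then medial, then superior
#' polygon (boundary inclusive, first match wins, so cells on a shared
#' boundary resolve basal-most). A cell falling in none of the three (a
#' numeric gap between the sampled polygons) is assigned to the layer with
#' the nearest boundary; the number of such fallbacks is returned in the
#' \code{"n_fallback"} attribute.
#'
#' @param cells a cells data frame (or a single \code{c(x, y)} point).
#' @param part a \code{strata_partition}.
#' @return Character vector of \code{"basal"}, \code{"medial"},
#'   \code{"superior"} per cell.
#' @export
assign_layer <- function(cells, part) {
  stopifnot(inherits(part, "strata_partition"))
  if (!is.data.frame(cells)) cells <- cells_df(cells[1], cells[2])
  layers <- c("basal", "medial", "superior")
  out <- character(nrow(cells))
  n_fallback <- 0L
  if (nrow(cells) > 0L) {
    inb <- point_in_polygon(cells$x, cells$y, part$basal, tol = 1e-7)
    inm <- point_in_polygon(cells$x, cells$y, part$medial, tol = 1e-7)
    ins <- point_in_polygon(cells$x, cells$y, part$superior, tol = 1e-7)
    for (i in seq_len(nrow(cells))) {
      hit <- c(inb[i], inm[i], ins[i])
      if (any(hit)) {
        out[i] <- layers[which(hit)[1]]
      } else {
        n_fallback <- n_fallback + 1L
        d2 <- c(.min_boundary_dist2(cells$x[i], cells$y[i], part$basal),
                .min_boundary_dist2(cells$x[i], cells$y[i], part$medial),
                .min_boundary_dist2(cells$x[i], cells$y[i], part$superior))
        out[i] <- layers[which.min(d2)]
      }
    }
  }
  attr(out, "n_fallback") <- n_fallback
  out
}
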