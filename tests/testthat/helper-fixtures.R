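# Shared fixtures and independent oracles. Everything is generated in code;
# expensive artefacts (scenes, detections, the Otsu triple table) are cached
# per session.

.fix <- new.env(parent = emptyenv())

# ---- raster fixtures -------------------------------------------------------

# binary matrix with a filled disc (0-based centre coordinates)
raster_disc <- function(h, w, cx, cy, r, value = 255L) {
  yy <- matrix(0:(h - 1), h, w); xx <- t(matrix(0:(w - 1), w, h))
  m <- matrix(0L, h, w)
  m[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- value
  m
}

raster_ring <- function(h, w, cx, cy, r_in, r_out) {
  yy <- matrix(0:(h - 1), h, w); xx <- t(matrix(0:(w - 1), w, h))
  m <- matrix(0L, h, w)
  d2 <- (xx - cx)^2 + (yy - cy)^2
  m[d2 >= r_in^2 & d2 <= r_out^2] <- 255L
  m
}

# lab_image built from explicit planes
lab_planes <- function(L, a, b) {
  structure(list(L = L, a = a, b = b), class = "lab_image")
}

# published 3-class confusion matrix (percent of cells; rows = true HIGH,
# LOW, NONE; columns = predicted)
published_cm <- function() {
  matrix(c(12.14, 3.60, 2.36,
           0.70, 9.15, 11.64,
           0.08, 1.80, 58.52),
         3, 3, byrow = TRUE,
         dimnames = list(c("HIGH", "LOW", "NONE"), c("HIGH", "LOW", "NONE")))
}

# ---- cached scenes ---------------------------------------------------------

std_scene <- function(seed = 1L) {
  key <- paste0("scene", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- render_scene(synth_params(seed = seed))
  .fix[[key]]
}

std_detection <- function(seed = 1L) {
  key <- paste0("det", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- detect_cells(std_scene(seed)$image, diameter_range(10, 40))
  .fix[[key]]
}

# high-only scene with near-uniform nucleus size (the distance-transform
# split retains cores of comparable scale)
high_scene <- function() {
  if (is.null(.fix$high_scene))
    .fix$high_scene <- render_scene(synth_params(n_high = 20, n_low = 0,
                                                 n_none = 0, d_min = 20,
                                                 d_max = 22, spacing = 1.2 * 26,
                                                 seed = 42))
  .fix$high_scene
}

# separable 3-class Lab-like feature table (means >= 10 sd apart)
separable_features <- function(n_per_class = 60, sd = 1.5, seed = 7) {
  set.seed(seed)
  means <- rbind(HIGH = c(60, 140, 160), LOW = c(120, 135, 150),
                 NONE = c(160, 130, 125))
  do.call(rbind, lapply(rownames(means), function(cl) {
    data.frame(mean_L = rnorm(n_per_class, means[cl, 1], sd),
               mean_a = rnorm(n_per_class, means[cl, 2], sd),
               mean_b = rnorm(n_per_class, means[cl, 3], sd),
               category = cl)
  }))
}

# ---- independent oracles ---------------------------------------------------

# exhaustive 3-threshold Otsu by minimizing total within-class variance over
# every ordered triple (independent derivation from the package's
# between-class maximization)
oracle_otsu3 <- function(img) {
  v <- as.integer(img)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  val <- 0:255
  C0 <- c(0, cumsum(p)); C1 <- c(0, cumsum(p * val)); C2 <- c(0, cumsum(p * val^2))
  if (is.null(.fix$oracle_triples)) {
    g <- expand.grid(t3 = 1:255, t2 = 1:255, t1 = 1:255)
    g <- g[g$t1 < g$t2 & g$t2 < g$t3, c("t1", "t2", "t3")]
    .fix$oracle_triples <- g  # rows in lexicographic (t1, t2, t3) order
  }
  g <- .fix$oracle_triples
  within <- function(lo, hi) {
    w <- C0[hi + 2L] - C0[lo + 1L]
    m <- C1[hi + 2L] - C1[lo + 1L]
    q <- C2[hi + 2L] - C2[lo + 1L]
    ifelse(w > 0, q - m^2 / w, 0)
  }
  n <- nrow(g)
  tot <- within(rep(0L, n), g$t1 - 1L) + within(g$t1, g$t2 - 1L) +
    within(g$t2, g$t3 - 1L) + within(g$t3, rep(255L, n))
  i <- which.min(tot)
  c(g$t1[i], g$t2[i], g$t3[i])
}

# even-odd point-in-polygon oracle (no boundary handling; use generic points)
oracle_point_in_polygon <- function(qx, qy, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > qy) != (yj > qy) &&
        qx < (xj - xi) * (qy - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# minimum-area enclosing rectangle by explicit per-hull-edge rotation
oracle_min_rect_area <- function(pts) {
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(hull)
  best <- Inf
  for (i in seq_len(n)) {
    e <- hull[(i %% n) + 1L, ] - hull[i, ]
    ang <- atan2(e[2], e[1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    rp <- hull %*% t(R)
    a <- (max(rp[, 1]) - min(rp[, 1])) * (max(rp[, 2]) - min(rp[, 2]))
    if (a < best) best <- a
  }
  best
}

# brute-force Euclidean distance transform (distance to nearest zero pixel)
oracle_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0L); bg <- which(mask == 0L)
  out <- matrix(0, h, w)
  if (length(fg) == 0L || length(bg) == 0L) return(out)
  fy <- (fg - 1L) %% h; fx <- (fg - 1L) %/% h
  by <- (bg - 1L) %% h; bx <- (bg - 1L) %/% h
  for (i in seq_along(fg))
    out[fg[i]] <- sqrt(min((bx - fx[i])^2 + (by - fy[i])^2))
  out
}

# random convex polygon in a bounding box
random_convex_polygon <- function(n_pts = 12, scale = 100) {
  pts <- cbind(runif(n_pts, 0, scale), runif(n_pts, 0, scale))
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

count_components8 <- function(mask) max(ihcscore:::.cc_label8(
  matrix(as.integer(mask != 0L), nrow(mask), ncol(mask))))
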