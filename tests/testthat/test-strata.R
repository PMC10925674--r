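test_that("minimum enclosing rectangle of a square is the square itself", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  r <- min_area_rect(sq)
  expect_equal(polygon_area(r), 100)
  expect_equal(r[1, ], c(x = 0, y = 0))   # starts nearest the first vertex
  # 45-degree rotated square: equal area, not the bounding box
  th <- pi / 4
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rot <- sq %*% t(R)
  r2 <- min_area_rect(rot)
  expect_equal(polygon_area(r2), 100, tolerance = 1e-9)
  expect_error(min_area_rect(rbind(c(0, 0), c(5, 5), c(10, 10))), "collinear")
})

test_that("rectangle area matches the hull-edge brute force on random polygons", {
  set.seed(71)
  for (rep in 1:50) {
    poly <- random_convex_polygon(n_pts = sample(5:20, 1))
    r <- min_area_rect(poly)
    area <- polygon_area(r)
    expect_equal(area, oracle_min_rect_area(poly), tolerance = 1e-9)
    bbox <- (max(poly[, 1]) - min(poly[, 1])) * (max(poly[, 2]) - min(poly[, 2]))
    expect_lte(area, bbox + 1e-9)
    # encloses every vertex
    expect_true(all(point_in_polygon(poly[, 1], poly[, 2], r, tol = 1e-6)))
  }
})

test_that("closest rectangle side is found, with ties to the lower index", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  r <- min_area_rect(sq)   # A=(0,0), B=(10,0), C=(10,10), D=(0,10)
  expect_equal(closest_rect_side(r, c(5, -5)), 0L)   # above AB
  expect_equal(closest_rect_side(r, c(15, 5)), 1L)   # right of BC
  expect_equal(closest_rect_side(r, c(5, 15)), 2L)   # below CD
  expect_equal(closest_rect_side(r, c(15, 15)), 1L)  # corner tie: BC before CD
  set.seed(72)
  for (rep in 1:100) {
    p <- runif(2, -30, 40)
    sides <- rbind(r, r[1, ])
    d <- vapply(1:4, function(i) {
      a <- sides[i, ]; b <- sides[i + 1, ]
      v <- b - a
      t <- max(0, min(1, sum((p - a) * v) / sum(v^2)))
      sum((a + t * v - p)^2)
    }, numeric(1))
    expect_equal(closest_rect_side(r, p), which.min(d) - 1L)
  }
})

test_that("a rectangular region partitions into three equal bands next to the basal point", {
  reg <- rbind(c(0, 0), c(300, 0), c(300, 90), c(0, 90))
  part <- partition_layers(reg, basal_point = c(150, 150), n_lines = 50)
  third <- polygon_area(reg) / 3
  for (p in list(part$basal, part$medial, part$superior))
    expect_lt(abs(polygon_area(p) - third) / third, 0.01)
  # basal band is the one nearest the basal point (y in [60, 90])
  expect_equal(assign_layer(cells_df(150, 75), part), "basal",
               ignore_attr = TRUE)
  expect_equal(assign_layer(cells_df(150, 45), part), "medial",
               ignore_attr = TRUE)
  expect_equal(assign_layer(cells_df(150, 15), part), "superior",
               ignore_attr = TRUE)
  expect_equal(part$n_skipped, 0L)
})

test_that("triangle layer areas and assignments match a rasterization oracle", {
  tri <- rbind(c(0, 0), c(200, 0), c(0, 120))
  part <- partition_layers(tri, basal_point = c(60, -40), n_lines = 100)
  # oracle: for x in the triangle, the vertical chord runs from y = 0 to
  # y = 120 (1 - x/200); thirds of the chord define the expected layer
  xs <- seq(0.5, 199.5, by = 1); ys <- seq(0.5, 119.5, by = 1)
  grid <- expand.grid(x = xs, y = ys)
  top <- 120 * (1 - grid$x / 200)
  inside <- grid$y < top & grid$x > 0
  g <- grid[inside, ]
  chord <- 120 * (1 - g$x / 200)
  expected <- ifelse(g$y < chord / 3, "basal",
                     ifelse(g$y < 2 * chord / 3, "medial", "superior"))
  got <- assign_layer(cells_df(g$x, g$y), part)
  expect_gt(mean(got == expected), 0.97)   # disagreement only at boundaries
  tri_area <- polygon_area(tri)
  for (l in c("basal", "medial", "superior")) {
    expect_lt(abs(sum(got == l) - sum(expected == l)) / (tri_area / 3), 0.02)
    expect_lt(abs(polygon_area(part[[l]]) - tri_area / 3) / (tri_area / 3), 0.02)
  }
})

test_that("layer areas sum to the region area within 2% on varied fixtures", {
  set.seed(73)
  fixtures <- list(
    rbind(c(0, 0), c(300, 0), c(300, 90), c(0, 90)),
    rbind(c(0, 0), c(200, 0), c(0, 120)),
    random_convex_polygon(8, 150),
    random_convex_polygon(14, 200),
    rbind(c(0, 0), c(100, 20), c(220, 0), c(240, 70), c(120, 95), c(-10, 80)))
  for (reg in fixtures) {
    ctr <- colMeans(reg)
    below <- c(ctr[1], max(reg[, 2]) + 50)
    part <- partition_layers(reg, below, n_lines = 100)
    tot <- polygon_area(part$basal) + polygon_area(part$medial) +
      polygon_area(part$superior)
    expect_lt(abs(tot - polygon_area(reg)) / polygon_area(reg), 0.02)
  }
})

test_that("region coverage by the layer union improves with more sweep lines", {
  reg <- rbind(c(0, 0), c(100, 20), c(220, 0), c(240, 70), c(120, 95), c(-10, 80))
  below <- c(115, 160)
  xs <- seq(min(reg[, 1]), max(reg[, 1]), by = 2)
  ys <- seq(min(reg[, 2]), max(reg[, 2]), by = 2)
  grid <- expand.grid(x = xs, y = ys)
  inside <- point_in_polygon(grid$x, grid$y, reg)
  g <- grid[inside, ]
  coverage <- vapply(c(10L, 40L, 160L), function(nl) {
    part <- partition_layers(reg, below, n_lines = nl)
    covered <- point_in_polygon(g$x, g$y, part$basal) |
      point_in_polygon(g$x, g$y, part$medial) |
      point_in_polygon(g$x, g$y, part$superior)
    mean(covered)
  }, numeric(1))
  expect_true(all(diff(coverage) >= 0))
  expect_gt(coverage[3], 0.97)
})

test_that("partitioning is equivariant under rigid motions", {
  reg <- rbind(c(0, 0), c(200, 0), c(0, 120))
  basal <- c(60, -40)
  set.seed(74)
  cells <- cells_df(runif(200, 5, 90), runif(200, 5, 50))
  keep <- point_in_polygon(cells$x, cells$y, reg)
  cells <- cells[keep, ]
  base <- assign_layer(cells, partition_layers(reg, basal, 100))
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  shift <- c(40, 60)
  rot <- function(m) sweep(m %*% t(R), 2, shift, `+`)
  reg_r <- rot(reg); basal_r <- as.vector(rot(rbind(basal)))
  cells_r <- cells; xy <- rot(as.matrix(cells[, c("x", "y")]))
  cells_r$x <- xy[, 1]; cells_r$y <- xy[, 2]
  moved <- assign_layer(cells_r, partition_layers(reg_r, basal_r, 100))
  expect_gt(mean(moved == base), 0.98)   # only boundary-grazing cells may flip
})

test_that("uniform cells land in the three layers in equal proportion", {
  reg <- rbind(c(0, 0), c(300, 0), c(300, 90), c(0, 90))
  part <- partition_layers(reg, c(150, 150), n_lines = 100)
  set.seed(75)
  cells <- cells_df(runif(1000, 1, 299), runif(1000, 1, 89))
  lay <- assign_layer(cells, part)
  for (l in c("basal", "medial", "superior"))
    expect_lt(abs(mean(lay == l) - 1 / 3), 0.05)
})

test_that("shared-boundary cells resolve basal-most", {
  reg <- rbind(c(0, 0), c(300, 0), c(300, 90), c(0, 90))
  part <- partition_layers(reg, c(150, 150), n_lines = 50)
  # a vertex of the basal/medial shared chain lies on both polygons
  v <- part$basal[nrow(part$basal), ]
  expect_equal(assign_layer(cells_df(v[1], v[2]), part), "basal",
               ignore_attr = TRUE)
})

test_that("regions with folds crossing the sweep are rejected", {
  # rectangle with a deep slot from the left: vertical sweep lines over the
  # slot cross the contour four times
  slot <- rbind(c(0, 0), c(100, 0), c(100, 90), c(0, 90), c(0, 50),
                c(60, 50), c(60, 40), c(0, 40))
  expect_error(partition_layers(slot, c(50, 140), n_lines = 50),
               "not epithelium-like")
})
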