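test_that("feature windows average the Lab planes with boundary clipping", {
  # constant image: features equal the colour anywhere
  flat <- lab_planes(matrix(40L, 8, 8), matrix(130L, 8, 8), matrix(90L, 8, 8))
  f <- extract_features(flat, cells_df(c(0, 7, 3), c(0, 7, 4)), d_min = 5)
  expect_true(all(f$mean_L == 40 & f$mean_a == 130 & f$mean_b == 90))
  # corner cell with s = 5: clipped 3 x 3 window, hand-computed
  L <- matrix(as.integer(1:25), 5, 5)   # column-major: L[y+1, x+1]
  lab <- lab_planes(L, matrix(0L, 5, 5), matrix(0L, 5, 5))
  f0 <- extract_features(lab, cells_df(0, 0), d_min = 5)
  expect_equal(f0$mean_L, mean(L[1:3, 1:3]))
  # half-dark / half-light window: mean midway between the two L values
  L2 <- cbind(matrix(10L, 6, 3), matrix(30L, 6, 3))
  lab2 <- lab_planes(L2, matrix(0L, 6, 6), matrix(0L, 6, 6))
  f2 <- extract_features(lab2, cells_df(2.2, 2.2), d_min = 6)
  expect_equal(f2$mean_L, 20)
})

test_that("training-set quotas split the cap with remainder to the first class", {
  feats <- data.frame(mean_L = 0, mean_a = 0, mean_b = 0,
                      category = rep(c("HIGH", "LOW", "NONE"), each = 500))
  ts <- build_training_set(feats, cap = 1000, seed = 1)
  take <- attr(ts, "class_take")
  expect_equal(unname(take), c(334L, 333L, 333L))
  expect_equal(nrow(ts), 1000L)
})

test_that("small classes are excluded or fully taken, with redistribution", {
  feats <- data.frame(mean_L = 0, mean_a = 0, mean_b = 0,
                      category = rep(c("HIGH", "LOW", "NONE"), c(2000, 50, 5)))
  ts <- build_training_set(feats, cap = 1000, min_per_class = 10, seed = 1)
  take <- attr(ts, "class_take")
  expect_equal(take[["HIGH"]], 950L)
  expect_equal(take[["LOW"]], 50L)
  expect_false("NONE" %in% names(take))
  expect_false("NONE" %in% ts$category)
  expect_equal(nrow(ts), 1000L)
  # cap not binding: everything is taken
  feats2 <- data.frame(mean_L = 0, mean_a = 0, mean_b = 0,
                       category = rep(c("HIGH", "LOW", "NONE"), each = 10))
  expect_equal(nrow(build_training_set(feats2, cap = 1000)), 30L)
  # nothing reaches the minimum
  feats3 <- data.frame(mean_L = 0, mean_a = 0, mean_b = 0,
                       category = rep(c("HIGH", "LOW"), each = 5))
  expect_error(build_training_set(feats3), "minimum")
})

test_that("kappa handles perfect, chance and published-table agreement", {
  expect_equal(cohen_kappa(diag(c(5, 8, 9))), 100)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohen_kappa(published_cm()), 60.21, tolerance = 0.1 / 60.21)
  # simultaneous row/column permutation leaves kappa unchanged
  set.seed(61)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 20), 3, 3)
    p <- sample(3)
    expect_equal(cohen_kappa(m[p, p]), cohen_kappa(m))
    expect_lte(cohen_kappa(m), 100)
  }
  # kappa is 100 iff all off-diagonal mass is zero
  m2 <- diag(c(3, 4, 5)); m2[1, 2] <- 1
  expect_lt(cohen_kappa(m2), 100)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
})

test_that("grid search recovers separable classes with near-perfect CV kappa", {
  ts <- separable_features(n_per_class = 60, sd = 1.5, seed = 7)
  model <- grid_search_train(ts, grid_spec(seed = 1))
  expect_gte(model$cv_kappa, 95)
  refit_acc <- mean(predict_features(model, ts) == ts$category)
  expect_equal(refit_acc, 1)
  # standardization constants reproduce the training moments
  X <- as.matrix(ts[, 1:3])
  expect_equal(unname(model$center), unname(colMeans(X)))
  expect_equal(unname(model$scale), unname(apply(X, 2, sd)))
})

test_that("identical feature distributions give near-zero CV kappa", {
  set.seed(8)
  n <- 50
  feats <- data.frame(mean_L = rnorm(2 * n, 100, 5),
                      mean_a = rnorm(2 * n, 128, 5),
                      mean_b = rnorm(2 * n, 128, 5),
                      category = rep(c("HIGH", "NONE"), each = n))
  # a single hyper-parameter pair keeps this quick; kappa stays near zero
  model <- grid_search_train(feats, grid_spec(lambdas = 2, sigmas = 2, seed = 1))
  expect_lt(abs(model$cv_kappa), 15)
})

test_that("a full tie selects the smallest lambda then sigma", {
  feats <- data.frame(mean_L = 1, mean_a = 2, mean_b = 3,
                      category = rep(c("HIGH", "LOW"), each = 20))
  grid <- grid_spec(lambdas = c(4, 1), sigmas = c(8, 2), seed = 1)
  model <- grid_search_train(feats, grid)
  expect_equal(model$lambda, 1)
  expect_equal(model$sigma, 2)
})

test_that("prediction is deterministic and preserves order; empty input passes through", {
  ts <- separable_features(seed = 9)
  model <- grid_search_train(ts, grid_spec(lambdas = c(1, 32),
                                           sigmas = c(0.5, 4), seed = 1))
  flat <- lab_planes(matrix(60L, 10, 10), matrix(140L, 10, 10),
                     matrix(160L, 10, 10))
  cells <- cells_df(c(2, 7, 5), c(2, 7, 5))
  p1 <- predict_cells(model, flat, cells, d_min = 4)
  p2 <- predict_cells(model, flat, cells, d_min = 4)
  expect_identical(p1, p2)
  expect_equal(p1$category, rep("HIGH", 3))   # the HIGH-class mean colour
  expect_equal(p1$x, cells$x)
  empty <- predict_cells(model, flat, cells_df(), d_min = 4)
  expect_equal(nrow(empty), 0L)
})

test_that("a fresh sample from the training distribution is classified accurately", {
  ts <- separable_features(n_per_class = 100, sd = 5, seed = 12)
  model <- grid_search_train(ts, grid_spec(seed = 2))
  fresh <- separable_features(n_per_class = 100, sd = 5, seed = 13)
  acc <- mean(predict_features(model, fresh) == fresh$category)
  expect_gte(acc, 0.95)
})

test_that("model text serialization round-trips predictions", {
  ts <- separable_features(seed = 15)
  model <- grid_search_train(ts, grid_spec(lambdas = c(1, 8),
                                           sigmas = c(0.5, 2), seed = 3))
  tf <- tempfile(fileext = ".txt")
  write_stain_model(model, tf)
  back <- read_stain_model(tf)
  probe <- separable_features(seed = 16)
  expect_equal(predict_features(back, probe), predict_features(model, probe))
  expect_equal(back$lambda, model$lambda)
  expect_equal(back$sigma, model$sigma)
  unlink(tf)
})

test_that("training requires at least two classes", {
  feats <- data.frame(mean_L = rnorm(30), mean_a = 0, mean_b = 0,
                      category = "HIGH")
  expect_error(grid_search_train(feats), "2 classes")
})
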