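test_that("detection matching handles exact, empty and ambiguous cases", {
  pts <- cells_df(c(10, 30, 50), c(10, 30, 50))
  expect_equal(match_detections(pts, pts, radius = 5),
               c(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(match_detections(cells_df(), pts, radius = 5),
               c(TP = 0L, FP = 0L, FN = 3L))
  expect_equal(match_detections(pts, cells_df(), radius = 5),
               c(TP = 0L, FP = 3L, FN = 0L))
})

test_that("greedy matching equals the optimal assignment on an ambiguous instance", {
  # two detections compete for one truth cell; a third pair is distant
  auto <- cells_df(c(0, 3, 40), c(0, 0, 0))
  truth <- cells_df(c(1.5, 41, 80), c(0, 0, 0))
  got <- match_detections(auto, truth, radius = 5)
  # brute force: enumerate all injective partial matchings within the radius
  d <- outer(auto$x, truth$x, `-`)^2 + outer(auto$y, truth$y, `-`)^2
  ok <- d <= 25
  n_best <- 0L
  assignments <- expand.grid(a1 = 0:3, a2 = 0:3, a3 = 0:3)
  for (r in seq_len(nrow(assignments))) {
    as_ <- unlist(assignments[r, ])
    used <- as_[as_ > 0]
    if (anyDuplicated(used)) next
    valid <- all(vapply(1:3, function(i) as_[i] == 0 || ok[i, as_[i]], logical(1)))
    if (valid) n_best <- max(n_best, length(used))
  }
  expect_equal(got[["TP"]], n_best)
  expect_equal(got, c(TP = 2L, FP = 1L, FN = 1L))
})

test_that("detection metrics follow the published ratio definitions", {
  expect_equal(detection_metrics(c(TP = 10, FP = 0, FN = 0)),
               c(Se = 100, Sp = 100, AP = 100))
  expect_equal(detection_metrics(c(TP = 6, FP = 2, FN = 4)),
               c(Se = 60, Sp = 75, AP = 50))
  expect_equal(detection_metrics(c(TP = 0, FP = 5, FN = 5)),
               c(Se = 0, Sp = 0, AP = 0))
  # zero denominators are undefined, not zero
  m <- detection_metrics(c(TP = 0, FP = 0, FN = 3))
  expect_true(is.na(m[["Sp"]]))
  expect_equal(m[["Se"]], 0)
  expect_error(detection_metrics(c(TP = 0, FP = 0, FN = 0)), "undefined")
})

test_that("detection metrics equal direct evaluation on 1000 random count triples", {
  set.seed(81)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp + fn == 0) next
    m <- detection_metrics(c(TP = tp, FP = fp, FN = fn))
    want <- c(Se = if (fn + tp > 0) 100 * tp / (fn + tp) else NA_real_,
              Sp = if (fp + tp > 0) 100 * tp / (fp + tp) else NA_real_,
              AP = 100 * tp / (tp + fp + fn))
    expect_identical(m, want)
  }
})

test_that("classification metrics reproduce the published three-class table", {
  res <- classification_metrics(published_cm())
  expect_equal(res$accuracy, 79.8, tolerance = 0.05 / 79.8)
  expect_equal(res$kappa, 60.21, tolerance = 0.1 / 60.21)
  pc <- res$per_class
  expect_equal(pc$Se[pc$class == "NONE"], 96.9, tolerance = 0.1 / 96.9)
  expect_equal(pc$Sp[pc$class == "NONE"], 80.7, tolerance = 0.1 / 80.7)
  expect_equal(pc$Se[pc$class == "LOW"], 42.6, tolerance = 0.1 / 42.6)
  expect_equal(pc$Sp[pc$class == "LOW"], 62.9, tolerance = 0.1 / 62.9)
  expect_equal(pc$Se[pc$class == "HIGH"], 67.1, tolerance = 0.1 / 67.1)
  expect_equal(pc$Sp[pc$class == "HIGH"], 94, tolerance = 0.1 / 94)
  ident <- classification_metrics(diag(c(2, 3, 4)))
  expect_true(all(ident$per_class$Se == 100 & ident$per_class$Sp == 100))
  expect_equal(ident$accuracy, 100)
  expect_equal(ident$kappa, 100)
})

test_that("accuracy is the row-weighted mean of per-class sensitivities", {
  set.seed(82)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 15) + 1, 3, 3,
                dimnames = list(c("HIGH", "LOW", "NONE"),
                                c("HIGH", "LOW", "NONE")))
    res <- classification_metrics(m)
    expect_equal(res$accuracy,
                 sum(res$per_class$Se * rowSums(m)) / sum(m))
  }
})

test_that("binarization groups classes and preserves identity structure", {
  b <- binarize_matrix(published_cm(), positive = "HIGH")
  expect_equal(dim(b), c(2L, 2L))
  expect_equal(sum(b), sum(published_cm()))
  acc <- classification_metrics(b)$accuracy
  expect_equal(acc, 93.26, tolerance = 0.01)
  expect_error(binarize_matrix(published_cm(),
                               positive = c("HIGH", "LOW", "NONE")),
               "proper subset")
  ident <- binarize_matrix(diag(c(2, 3, 4)) +
                             0 * published_cm(),  # reuse dimnames
                           positive = "HIGH")
  expect_true(all(ident[row(ident) != col(ident)] == 0))
})

test_that("quantification conserves counts across layers and flags unlabelled cells", {
  reg <- rbind(c(0, 0), c(300, 0), c(300, 90), c(0, 90))
  part <- partition_layers(reg, c(150, 150), n_lines = 50)
  # 5 HIGH cells in the basal band (y in [60, 90]) only
  cells <- cells_df(c(seq(30, 270, length.out = 5), seq(40, 260, length.out = 7)),
                    c(rep(75, 5), rep(20, 7)),
                    category = c(rep("HIGH", 5), rep("NONE", 7)))
  ov <- overlay("img", 320, 120, reg, cells = cells, basal = c(150, 150))
  res <- quantify(ov, part)
  expect_equal(res$n_high[res$layer == "basal"], 5L)
  expect_equal(res$n_high[res$layer == "medial"], 0L)
  expect_equal(res$n_high[res$layer == "superior"], 0L)
  for (cat in c("n_high", "n_low", "n_none", "n_positive"))
    expect_equal(sum(res[[cat]][res$layer != "all"]), res[[cat]][res$layer == "all"])
  rows <- res[res$n_total > 0, ]
  expect_equal(rows$pct_high + rows$pct_low + rows$pct_none,
               rep(100, nrow(rows)))
  # positivity definitions
  expect_equal(res$pct_positive[res$layer == "all"], 100 * 5 / 12)
  res_high <- quantify(ov, positive = "HIGH")
  expect_equal(res_high$n_positive, 5L)
  ov_bad <- overlay("img", 320, 120, reg,
                    cells = cells_df(10, 10, NA_character_))
  expect_error(quantify(ov_bad), "1 cell")
})
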