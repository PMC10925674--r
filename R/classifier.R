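# Stain-intensity classification: Lab-mean features, quota-balanced training
# set, RBF-kernel SVM with (lambda, sigma) grid search by 4-fold CV kappa.

#' Lab-mean features of cells
#'
#' For each cell, a square window of side \code{s = max(3, round(d_min))}
#' centred at the rounded cell coordinates (clipped to the image bounds) is
#' taken from the 8-bit Lab image, and the arithmetic means of the L, a and b
#' planes over the window are the three features.
#'
#' @param lab a \code{lab_image}.
#' @param cells a cells data frame.
#' @param d_min minimum cell diameter in pixels (window size).
#' @return Data frame with columns \code{mean_L}, \code{mean_a},
#'   \code{mean_b} (one row per cell, input order preserved).
#' @export
extract_features <- function(lab, cells, d_min) {
  stopifnot(inherits(lab, "lab_image"))
  s <- max(3L, as.integer(round(d_min)))
  lo <- (s - 1L) %/% 2L
  hi <- s %/% 2L
  h <- nrow(lab$L); w <- ncol(lab$L)
  n <- nrow(cells)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    cx <- as.integer(round(cells$x[i])); cy <- as.integer(round(cells$y[i]))
    if (cx < 0L || cx >= w || cy < 0L || cy >= h)
      stop("cell ", i, " lies outside the image")
    xs <- max(0L, cx - lo):min(w - 1L, cx + hi) + 1L
    ys <- max(0L, cy - lo):min(h - 1L, cy + hi) + 1L
    out[i, ] <- c(mean(lab$L[ys, xs]), mean(lab$a[ys, xs]), mean(lab$b[ys, xs]))
  }
  data.frame(mean_L = out[, 1], mean_a = out[, 2], mean_b = out[, 3])
}

#' Features and labels for an overlay's cells
#'
#' Convenience wrapper joining \code{\link{extract_features}} on an overlay's
#' cells with their categories, for assembling training data from a
#' collection of supervised overlays.
#'
#' @param ov an \code{ihc_overlay} with categorized cells.
#' @param lab the \code{lab_image} of the overlay's image.
#' @return Data frame \code{mean_L}, \code{mean_a}, \code{mean_b},
#'   \code{category}.
#' @export
overlay_features <- function(ov, lab) {
  stopifnot(inherits(ov, "ihc_overlay"))
  f <- extract_features(lab, ov$cells, ov$diameters[["d_min"]])
  f$category <- ov$cells$category
  f
}

#' Build a capped, class-balanced training set
#'
#' Classes with fewer than \code{min_per_class} labelled cells are excluded.
#' The remaining classes share the \code{cap} as equally as possible: each
#' gets a quota of \code{floor(cap / k)} (the remainder going one-by-one to
#' the earlier classes in HIGH, LOW, NONE order); classes with fewer members
#' than their quota contribute everything and the shortfall is redistributed
#' equally among classes that still have members to spare. Sampling within a
#' class is without replacement under the given seed.
#'
#' @param features data frame with columns \code{mean_L}, \code{mean_a},
#'   \code{mean_b}, \code{category} (e.g. row-bound
#'   \code{\link{overlay_features}} outputs).
#' @param cap maximum total number of training cells (default 1000).
#' @param min_per_class minimum class size for inclusion (default 10).
#' @param seed RNG seed for the subsampling.
#' @return Data frame of the sampled rows (same columns), with the per-class
#'   take in attribute \code{"class_take"}.
#' @export
build_training_set <- function(features, cap = 1000L, min_per_class = 10L,
                               seed = 1L) {
  stopifnot(is.data.frame(features), "category" %in% names(features))
  features <- features[!is.na(features$category), , drop = FALSE]
  classes <- intersect(.stain_levels, unique(features$category))
  avail <- vapply(classes, function(cl) sum(features$category == cl), integer(1))
  keep <- avail >= min_per_class
  if (!any(keep))
    stop("no class reaches the minimum of ", min_per_class, " labelled cells")
  classes <- classes[keep]; avail <- avail[keep]
  k <- length(classes)
  total <- min(cap, sum(avail))
  quota <- rep(total %/% k, k)
  rem <- total - sum(quota)
  if (rem > 0L) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  # redistribute shortfalls of small classes to classes with spare members
  repeat {
    take <- pmin(quota, avail)
    leftover <- total - sum(take)
    spare <- avail - take
    if (leftover <= 0L || !any(spare > 0L)) break
    idx <- which(spare > 0L)
    add <- rep(leftover %/% length(idx), length(idx))
    r <- leftover - sum(add)
    if (r > 0L) add[seq_len(r)] <- add[seq_len(r)] + 1L
    quota <- take
    quota[idx] <- quota[idx] + add
  }
  take <- pmin(quota, avail)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  rows <- unlist(lapply(seq_along(classes), function(j) {
    cand <- which(features$category == classes[j])
    if (take[j] >= length(cand)) cand else sort(sample(cand, take[j]))
  }))
  out <- features[rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_take") <- stats::setNames(take, classes)
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Confusion matrix of true vs predicted categories
#'
#' @param truth,pred vectors of category labels.
#' @param levels category levels fixing the matrix order; defaults to the
#'   union of observed labels in HIGH, LOW, NONE order.
#' @return Square matrix of counts, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred,
                             levels = intersect(.stain_levels,
                                                unique(c(truth, pred)))) {
  if (length(levels) == 0L) levels <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- unclass(as.matrix(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Cohen's kappa (in percent)
#'
#' Chance-corrected agreement between the row (true) and column (predicted)
#' labelling of a confusion matrix: \code{100 (p_o - p_e) / (1 - p_e)} with
#' observed agreement \code{p_o} (normalized trace) and chance agreement
#' \code{p_e} (sum of row-marginal times column-marginal products). Entries
#' may be counts or nonnegative weights (e.g. percentages). Returns 0 when
#' \code{p_e = 1} (a single occupied category on both sides).
#'
#' @param cm square numeric matrix, rows = true, columns = predicted.
#' @return Kappa in percent (at most 100).
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  N <- sum(cm)
  if (N <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (abs(1 - pe) < 1e-12) return(0)
  100 * (po - pe) / (1 - pe)
}

#' Hyper-parameter grid for the SVM
#'
#' @param lambdas regularization values; default \code{2^(2i - 7)} for
#'   \code{i = 1..10} (i.e. 2^-5 ... 2^13).
#' @param sigmas RBF kernel spreads; default \code{2^(-(i + 1)/2)} for
#'   \code{i = -15..0} (i.e. 2^7 ... 2^-0.5).
#' @param folds number of cross-validation folds (default 4).
#' @param seed RNG seed for the stratified fold split.
#' @return Named list of grid settings.
#' @export
grid_spec <- function(lambdas = 2^(2 * (1:10) - 7),
                      sigmas = 2^(-((-15:0) + 1) / 2),
                      folds = 4L, seed = 1L) {
  stopifnot(length(lambdas) > 0, length(sigmas) > 0, folds >= 2L)
  list(lambdas = sort(lambdas), sigmas = sort(sigmas),
       folds = as.integer(folds), seed = as.integer(seed))
}

.fit_svm <- function(X, y, lambda, sigma) {
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             cost = lambda, gamma = 1 / (2 * sigma^2), scale = FALSE)
}

#' Train the stain classifier by cross-validated grid search
#'
#' Features are standardized by the training mean and standard deviation (the
#' constants are stored in the model). For every (lambda, sigma) pair of the
#' grid a stratified \code{folds}-fold cross-validation is run: the SVM is
#' trained on the other folds and Cohen's kappa is measured on the held-out
#' fold, rotating and averaging. The pair with the highest mean kappa wins
#' (ties prefer the smaller lambda, then the smaller sigma); the final model
#' is refit on the whole training set with the winning pair.
#'
#' @param ts training data frame (\code{mean_L}, \code{mean_a},
#'   \code{mean_b}, \code{category}) with at least two classes.
#' @param grid a \code{\link{grid_spec}}.
#' @return An object of class \code{ihc_svm} holding the fitted SVM, the
#'   standardization constants, the winning hyper-parameters, the CV results
#'   table and the training data (kept so the model can be re-fit from its
#'   text serialization).
#' @export
grid_search_train <- function(ts, grid = grid_spec()) {
  stopifnot(is.data.frame(ts), nrow(ts) >= 2L)
  y_all <- factor(ts$category, levels = intersect(.stain_levels, unique(ts$category)))
  if (nlevels(y_all) < 2L) stop("training requires at least 2 classes")
  X <- as.matrix(ts[, c("mean_L", "mean_a", "mean_b")])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  # stratified fold assignment, seeded
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(grid$seed)
  fold <- integer(nrow(Xs))
  for (cl in levels(y_all)) {
    idx <- which(y_all == cl)
    fold[idx] <- sample(rep_len(seq_len(grid$folds), length(idx)))
  }
  lev <- levels(y_all)
  cv <- expand.grid(lambda = grid$lambdas, sigma = grid$sigmas,
                    KEEP.OUT.ATTRS = FALSE)
  cv$kappa <- NA_real_
  best <- list(kappa = -Inf, lambda = NA, sigma = NA)
  for (r in seq_len(nrow(cv))) {
    lam <- cv$lambda[r]; sig <- cv$sigma[r]
    ks <- vapply(seq_len(grid$folds), function(f) {
      tr <- fold != f
      if (length(unique(y_all[tr])) < 2L || !any(!tr)) return(NA_real_)
      m <- .fit_svm(Xs[tr, , drop = FALSE], droplevels(y_all[tr]), lam, sig)
      pr <- as.character(stats::predict(m, Xs[!tr, , drop = FALSE]))
      cohen_kappa(confusion_matrix(as.character(y_all[!tr]), pr, levels = lev))
    }, numeric(1))
    cv$kappa[r] <- mean(ks, na.rm = TRUE)
    better <- cv$kappa[r] > best$kappa + 1e-9 ||
      (abs(cv$kappa[r] - best$kappa) <= 1e-9 &&
         (lam < best$lambda || (lam == best$lambda && sig < best$sigma)))
    if (better) best <- list(kappa = cv$kappa[r], lambda = lam, sigma = sig)
  }
  fit <- .fit_svm(Xs, y_all, best$lambda, best$sigma)
  structure(list(svm = fit, center = ctr, scale = scl,
                 lambda = best$lambda, sigma = best$sigma,
                 cv_kappa = best$kappa, cv = cv, levels = lev,
                 training = ts[, c("mean_L", "mean_a", "mean_b", "category")],
                 grid_seed = grid$seed),
            class = "ihc_svm")
}

#' @export
print.ihc_svm <- function(x, ...) {
  cat(sprintf("<ihc_svm> RBF SVM on %d cells (%s); lambda = %g, sigma = %g, mean CV kappa = %.1f\n",
              nrow(x$training), paste(x$levels, collapse = "/"),
              x$lambda, x$sigma, x$cv_kappa))
  invisible(x)
}

#' Predict stain categories on a feature table
#'
#' @param model an \code{ihc_svm}.
#' @param features data frame with \code{mean_L}, \code{mean_a},
#'   \code{mean_b}.
#' @return Character vector of predicted categories.
#' @export
predict_features <- function(model, features) {
  stopifnot(inherits(model, "ihc_svm"))
  if (nrow(features) == 0L) return(character(0))
  X <- as.matrix(features[, c("mean_L", "mean_a", "mean_b")])
  Xs <- scale(X, center = model$center, scale = model$scale)
  as.character(stats::predict(model$svm, Xs))
}

#' Classify detected cells on an image
#'
#' Extracts Lab-mean features for each cell and sets its category to the
#' model's prediction; input order is preserved.
#'
#' @param model an \code{ihc_svm}.
#' @param lab the image's \code{lab_image}.
#' @param cells a cells data frame.
#' @param d_min feature window size (minimum cell diameter, pixels).
#' @return The cells data frame with \code{category} filled in.
#' @export
predict_cells <- function(model, lab, cells, d_min) {
  if (nrow(cells) == 0L) return(cells)
  f <- extract_features(lab, cells, d_min)
  cells$category <- predict_features(model, f)
  cells
}

#' Write / read a stain classifier as a portable text file
#'
#' The serialization stores the standardization constants, the selected
#' hyper-parameters and the full training table; reading re-fits the SVM,
#' which is deterministic, so a round trip reproduces identical predictions.
#'
#' @param model an \code{ihc_svm}.
#' @param path destination file.
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "ihc_svm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ihc_svm 1",
               paste("lambda", .fmt_coord(model$lambda)),
               paste("sigma", .fmt_coord(model$sigma)),
               paste("center", paste(.fmt_coord(model$center), collapse = " ")),
               paste("scale", paste(.fmt_coord(model$scale), collapse = " ")),
               paste("grid_seed", model$grid_seed),
               "training"), con)
  utils::write.csv(model$training, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stain_model
#' @return \code{read_stain_model} returns the re-fitted \code{ihc_svm}.
#' @export
read_stain_model <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ihc_svm 1") stop("not an ihc_svm model file")
  kv <- function(key) strsplit(sub(paste0("^", key, " "), "",
                                   grep(paste0("^", key, " "), lines, value = TRUE)[1]),
                               " ")[[1]]
  lambda <- as.numeric(kv("lambda")); sigma <- as.numeric(kv("sigma"))
  ti <- which(lines == "training")[1]
  ts <- utils::read.csv(text = paste(lines[(ti + 1L):length(lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  grid_search_train(ts, grid_spec(lambdas = lambda, sigmas = sigma,
                                  seed = as.integer(kv("grid_seed"))))
}
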