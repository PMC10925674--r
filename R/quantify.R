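# Evaluation metrics (detection and classification) and per-stratum
# positivity quantification with CSV export.

#' Match automatic detections to ground truth
#'
#' Greedy one-to-one matching in increasing distance order: all
#' (detection, truth) pairs within \code{radius} are sorted by distance and
#' accepted when neither member is already matched. Matched pairs are true
#' positives, unmatched detections false positives, unmatched truth cells
#' false negatives.
#'
#' @param auto,truth cells data frames.
#' @param radius maximum matching distance in pixels (typically
#'   \code{d_min}).
#' @return Named integer vector \code{c(TP, FP, FN)}.
#' @export
match_detections <- function(auto, truth, radius) {
  stopifnot(radius > 0)
  na <- nrow(auto); nt <- nrow(truth)
  if (na == 0L || nt == 0L)
    return(c(TP = 0L, FP = na, FN = nt))
  d <- outer(auto$x, truth$x, `-`)^2 + outer(auto$y, truth$y, `-`)^2
  cand <- which(d <= radius^2, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand) > 0L) {
    ord <- order(d[cand])
    used_a <- logical(na); used_t <- logical(nt)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_t[j]) {
        used_a[i] <- TRUE; used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(TP = tp, FP = na - tp, FN = nt - tp)
}

#' Detection metrics: sensitivity, specificity, average precision
#'
#' \code{Se = 100 TP / (FN + TP)}, \code{Sp = 100 TP / (FP + TP)} and
#' \code{AP = 100 TP / (TP + FP + FN)}. Note that the quantity reported as
#' specificity here is mathematically the positive predictive value
#' (precision): detection has no true-negative count, and the name follows
#' the convention of the quantification protocol this package implements.
#' A ratio with a zero denominator is reported as \code{NA} (undefined),
#' never coerced to 0 or 100.
#'
#' @param counts named vector with elements \code{TP}, \code{FP}, \code{FN}.
#' @return Named numeric vector \code{c(Se, Sp, AP)} in percent.
#' @export
detection_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) stop("undefined metrics: TP, FP and FN are all zero")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(Se = ratio(tp, fn + tp), Sp = ratio(tp, fp + tp),
    AP = ratio(tp, tp + fp + fn))
}

#' Per-class classification metrics
#'
#' For each class i of a confusion matrix (rows = true, columns = predicted):
#' sensitivity \code{Se_i = 100 N_ii / row_i} and specificity
#' \code{Sp_i = 100 N_ii / col_i} (again the per-class predictive value, per
#' the reporting convention), overall accuracy (normalized trace, in percent)
#' and Cohen's kappa. Empty rows or columns yield \code{NA} for that class.
#'
#' @param cm square numeric matrix (counts or weights).
#' @return List with \code{per_class} (data frame of Se, Sp),
#'   \code{accuracy} and \code{kappa}.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  N <- sum(cm)
  if (N <= 0) stop("empty confusion matrix")
  rs <- rowSums(cm); cs <- colSums(cm)
  se <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  sp <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  list(per_class = data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                              Se = as.numeric(se), Sp = as.numeric(sp)),
       accuracy = 100 * sum(diag(cm)) / N,
       kappa = cohen_kappa(cm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse a confusion matrix to positive vs negative
#'
#' @param cm square matrix with row/column names equal to the categories.
#' @param positive character vector of categories treated as positive; must
#'   be a nonempty proper subset of the classes.
#' @return 2 x 2 matrix with rows/columns \code{positive}, \code{negative}.
#' @export
binarize_matrix <- function(cm, positive = "HIGH") {
  cm <- as.matrix(cm)
  classes <- rownames(cm)
  if (is.null(classes)) stop("confusion matrix must have class names")
  if (length(positive) == 0L || !all(positive %in% classes) ||
      length(positive) >= length(classes))
    stop("`positive` must be a nonempty proper subset of the classes")
  grp <- ifelse(classes %in% positive, "positive", "negative")
  m <- rowsum(t(rowsum(cm, grp)), grp)
  m <- m[c("positive", "negative"), c("positive", "negative")]
  m
}

#' Per-layer positivity quantification
#'
#' Counts cells per stain category, globally (layer \code{"all"}) and, when a
#' strata partition is supplied, per basal/medial/superior layer. A cell is
#' positive when its category belongs to \code{positive} (default both
#' stained levels, \code{HIGH} and \code{LOW}; restrict to \code{"HIGH"} for
#' a strong-staining-only definition).
#'
#' @param ov an \code{ihc_overlay} whose cells are all categorized.
#' @param part optional \code{strata_partition}.
#' @param positive categories counted as positive.
#' @return Data frame with one row per layer: \code{image_id}, \code{layer},
#'   \code{n_high}, \code{n_low}, \code{n_none}, \code{n_total},
#'   \code{pct_high}, \code{pct_low}, \code{pct_none}, \code{n_positive},
#'   \code{pct_positive}.
#' @export
quantify <- function(ov, part = NULL, positive = c("HIGH", "LOW")) {
  stopifnot(inherits(ov, "ihc_overlay"))
  cells <- ov$cells
  if (anyNA(cells$category))
    stop(sum(is.na(cells$category)), " cell(s) have no category; ",
         "classify or label them before quantification")
  stopifnot(all(positive %in% .stain_levels))
  one_layer <- function(sub, layer) {
    n <- c(HIGH = sum(sub$category == "HIGH"),
           LOW = sum(sub$category == "LOW"),
           NONE = sum(sub$category == "NONE"))
    tot <- sum(n)
    pct <- if (tot > 0) 100 * n / tot else c(HIGH = NA_real_, LOW = NA_real_,
                                             NONE = NA_real_)
    npos <- sum(n[positive])
    data.frame(image_id = ov$image_id, layer = layer,
               n_high = n[["HIGH"]], n_low = n[["LOW"]], n_none = n[["NONE"]],
               n_total = tot,
               pct_high = pct[["HIGH"]], pct_low = pct[["LOW"]],
               pct_none = pct[["NONE"]],
               n_positive = npos,
               pct_positive = if (tot > 0) 100 * npos / tot else NA_real_)
  }
  out <- one_layer(cells, "all")
  if (!is.null(part)) {
    lay <- assign_layer(cells, part)
    for (l in c("basal", "medial", "superior"))
      out <- rbind(out, one_layer(cells[lay == l, , drop = FALSE], l))
  }
  rownames(out) <- NULL
  out
}

#' Write quantification results to CSV
#'
#' One row per (image, layer), comma separated, "." decimal point, UTF-8,
#' header row; percentages are printed with 2 decimals.
#'
#' @param results row-bound \code{\link{quantify}} outputs (nonempty).
#' @param path destination file.
#' @export
write_results_csv <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  out <- results
  for (col in grep("^pct_", names(out), value = TRUE))
    out[[col]] <- sprintf("%.2f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a detection evaluation report to CSV
#'
#' @param report data frame with columns \code{image_id}, \code{TP},
#'   \code{FP}, \code{FN}, \code{Se}, \code{Sp}, \code{AP}.
#' @param path destination file.
#' @export
write_evaluation_csv <- function(report, path) {
  stopifnot(is.data.frame(report), nrow(report) > 0L)
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
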