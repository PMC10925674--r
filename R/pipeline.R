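# Accumulation of detections across channels with duplicate suppression and
# restriction to the user-drawn analysis region.

.channel_order <- c("RDA_HIGH", "RDA_LOW", "RDA_WS", "EDA")

#' Merge detections from several channels with duplicate suppression
#'
#' Candidates are visited greedily in fixed channel precedence order
#' (RDA_HIGH, then RDA_LOW, RDA_WS, EDA; within a channel, extraction order)
#' and kept only when their Euclidean distance to every already-kept cell is
#' strictly greater than \code{d_min}. Two points closer than the minimum
#' cell diameter cannot be two different cells, so the later (lower-priority)
#' one is dropped. The greedy rule is deterministic and idempotent; it does
#' not attempt a maximum-cardinality selection.
#'
#' @param bundle named list of cells data frames, one per channel; names must
#'   be among \code{RDA_HIGH}, \code{RDA_LOW}, \code{RDA_WS}, \code{EDA}.
#'   A single unnamed data frame is also accepted.
#' @param d_min suppression radius in pixels (> 0).
#' @return A cells data frame whose pairwise distances all exceed
#'   \code{d_min}.
#' @export
merge_point_sets <- function(bundle, d_min) {
  stopifnot(d_min > 0)
  if (is.data.frame(bundle)) bundle <- list(bundle)
  if (!is.null(names(bundle))) {
    known <- names(bundle) %in% .channel_order
    if (!all(known | names(bundle) == ""))
      stop("unknown channel: ", paste(names(bundle)[!known], collapse = ", "))
    ord <- order(match(names(bundle), .channel_order, nomatch = length(.channel_order) + 1L))
    bundle <- bundle[ord]
  }
  all_cells <- do.call(rbind, c(bundle, list(make.row.names = FALSE)))
  if (is.null(all_cells) || nrow(all_cells) == 0L) return(cells_df())
  kept <- logical(nrow(all_cells))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(all_cells))) {
    if (length(kx) == 0L ||
        all((kx - all_cells$x[i])^2 + (ky - all_cells$y[i])^2 > d_min^2)) {
      kept[i] <- TRUE
      kx <- c(kx, all_cells$x[i]); ky <- c(ky, all_cells$y[i])
    }
  }
  out <- all_cells[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict cells to the analysis region
#'
#' Keeps cells strictly inside or on the boundary of the polygon (even-odd
#' rule; a cell on the outline the user drew is not silently dropped).
#'
#' @param cells a cells data frame.
#' @param region an n x 2 vertex matrix (implicitly closed, simple).
#' @return The subset of \code{cells} inside the region.
#' @export
filter_to_region <- function(cells, region) {
  p <- .validate_region(region)
  if (nrow(cells) == 0L) return(cells)
  keep <- point_in_polygon(cells$x, cells$y, p)
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full detection pipeline over selected channels
#'
#' Runs the region-based detector on the requested channels and/or the
#' edge-based detector, merges the channels with duplicate suppression at
#' \code{d_min}, and restricts the result to the analysis region when one is
#' given.
#'
#' @param img an \code{ihc_image}.
#' @param rng a \code{\link{diameter_range}} in pixels.
#' @param channels character subset of
#'   \code{c("RDA_HIGH", "RDA_LOW", "RDA_WS", "EDA")}.
#' @param region optional analysis polygon.
#' @param eda an \code{\link{eda_params}} list.
#' @return A cells data frame.
#' @export
detect_cells <- function(img, rng,
                         channels = c("RDA_HIGH", "RDA_LOW", "RDA_WS", "EDA"),
                         region = NULL, eda = eda_params()) {
  channels <- match.arg(channels, .channel_order, several.ok = TRUE)
  bundle <- list()
  rda_channels <- intersect(channels, c("RDA_HIGH", "RDA_LOW", "RDA_WS"))
  if (length(rda_channels) > 0L) {
    lab <- rgb_to_lab(img)
    for (ch in rda_channels) {
      opt <- sub("^RDA_", "", ch)
      bundle[[ch]] <- rda_detect(img, rng, option = opt, lab = lab)
    }
  }
  if ("EDA" %in% channels) bundle[["EDA"]] <- eda_detect(img, rng, params = eda)
  merged <- merge_point_sets(bundle, rng[["d_min"]])
  if (!is.null(region)) merged <- filter_to_region(merged, region)
  merged
}
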