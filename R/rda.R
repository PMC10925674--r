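# Region-detection algorithm (RDA): Lab preprocessing, multi-level Otsu,
# seeded colour clustering, distance-transform splitting and contour-based
# cell extraction.

.as_ebimage_binary <- function(mask) EBImage::Image(mask / 255)

#' Split touching strongly stained regions with the distance transform
#'
#' Computes the exact Euclidean distance transform of the mask (distance of
#' each foreground pixel to the nearest background pixel), normalizes it to
#' \code{[0, 255]} and keeps only pixels whose normalized distance exceeds
#' the highest of the three Otsu thresholds computed on the histogram of the
#' nonzero normalized distances. Touching convex blobs separate because the
#' distance ridge between them is shallow. An empty mask (or one with a
#' degenerate distance histogram) returns an all-black mask.
#'
#' @param mask binary matrix (0/255).
#' @return Binary matrix (0/255), a subset of the input foreground.
#' @export
split_joined_high <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask == 255L)) return(out)
  D <- EBImage::distmap(.as_ebimage_binary(mask), metric = "euclidean")@.Data
  Dmax <- max(D)
  if (Dmax <= 0) return(out)
  Dn <- round(255 * D / Dmax)
  nz <- Dn[Dn > 0]
  t3 <- tryCatch(otsu3_thresholds(nz)[["t3"]],
                 error = function(e) NA_integer_)
  if (is.na(t3)) return(out)
  out[Dn > t3] <- 255L
  out
}

#' Extract cell points from a binary mask
#'
#' Labels the 8-connected foreground regions of the mask (holes are filled
#' first, so only external contours matter), computes each region's pixel
#' area \code{A} and equivalent-circle diameter \code{d = 2 sqrt(A / pi)},
#' and keeps regions with \code{d_min < d < d_max} (strict on both sides).
#' Each kept region becomes one cell at its area centroid, with the category
#' unset and the given source tag.
#'
#' @param mask binary matrix (0/255).
#' @param rng a \code{\link{diameter_range}} in pixels.
#' @param source detector tag recorded on the cells.
#' @return A cells data frame (see \code{\link{cells_df}}).
#' @export
extract_cells <- function(mask, rng, source = "MANUAL") {
  if (!any(mask == 255L)) return(cells_df())
  filled <- EBImage::fillHull(.as_ebimage_binary(mask))@.Data
  lab <- .cc_label8(matrix(as.integer(filled > 0.5), nrow(mask), ncol(mask)))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(cells_df())
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask)        # 0-based y
  cols <- (idx - 1L) %/% nrow(mask)       # 0-based x
  area <- tabulate(labs)
  cx <- rowsum(as.numeric(cols), labs)[, 1] / area
  cy <- rowsum(as.numeric(rows), labs)[, 1] / area
  d <- 2 * sqrt(area / pi)
  keep <- d > rng[["d_min"]] & d < rng[["d_max"]]
  cells_df(cx[keep], cy[keep], NA_character_, source)
}

#' Region-based cell detection
#'
#' Runs the full region-detection chain on an RGB image: CIELAB conversion,
#' grey projection (normalized L*b product), three-level Otsu thresholding of
#' the grey image (lowest threshold, values below it are foreground), seeded
#' 4-cluster k-means on the Lab pixels, then per-channel post-processing.
#' Cluster 1 gathers the strongly stained pixels and, for
#' \code{option = "HIGH"}, is split with the distance transform before cell
#' extraction; clusters 2 and 3 (low stained / unstained colours) are closed
#' morphologically and extracted directly for \code{"LOW"} and \code{"WS"}.
#'
#' A blank image (fewer than 4 distinct grey values, or a degenerate seed)
#' yields an empty cell list rather than an error.
#'
#' @param img an \code{ihc_image}.
#' @param rng a \code{\link{diameter_range}} in pixels.
#' @param option detection channel: \code{"HIGH"}, \code{"LOW"} or
#'   \code{"WS"} (without staining).
#' @param lab optional precomputed \code{lab_image} of \code{img}.
#' @return A cells data frame.
#' @export
rda_detect <- function(img, rng, option = c("HIGH", "LOW", "WS"), lab = NULL) {
  option <- match.arg(option)
  if (is.null(lab)) lab <- rgb_to_lab(img)
  grey <- grey_from_lab(lab)
  thr <- tryCatch(otsu3_thresholds(grey), error = function(e) NULL)
  if (is.null(thr)) return(cells_df())
  bin <- threshold_below(grey, thr[["t1"]])
  if (!any(bin == 255L) || all(bin == 255L)) return(cells_df())
  labels <- seeded_kmeans4(lab, bin)
  if (option == "HIGH") {
    mask <- cluster_mask(labels, 1L, close = FALSE)
    mask <- split_joined_high(mask)
    extract_cells(mask, rng, source = "RDA_HIGH")
  } else if (option == "LOW") {
    mask <- cluster_mask(labels, 2L, close = TRUE)
    extract_cells(mask, rng, source = "RDA_LOW")
  } else {
    mask <- cluster_mask(labels, 3L, close = TRUE)
    extract_cells(mask, rng, source = "RDA_WS")
  }
}
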