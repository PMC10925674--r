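# Edge-detection approach (EDA): Canny filtering with derivative-of-Gaussian
# gradients and automatic hysteresis thresholds from gradient-magnitude
# quantiles, followed by conversion of closed edge regions to cell points.

#' Parameters of the edge-based detector
#'
#' @param sigma Gaussian smoothing width in pixels (default 4).
#' @param low_rate,high_rate rates (defaults 0.3 and 0.7) multiplying the
#'   automatically determined reference gradient magnitude to give the low
#'   and high hysteresis thresholds. The reference is the Otsu threshold of
#'   the gradient-magnitude distribution, i.e. the level that best separates
#'   the flat/noise gradients from structural edges, so the thresholds adapt
#'   to image content and are covariant under affine intensity rescaling.
#' @return A named list of validated parameters.
#' @export
eda_params <- function(sigma = 4.0, low_rate = 0.3, high_rate = 0.7) {
  stopifnot(sigma > 0, low_rate > 0, low_rate < high_rate, high_rate <= 1)
  list(sigma = sigma, low_rate = low_rate, high_rate = high_rate)
}

# 1-D convolution along rows / columns with replicate padding
.conv_along_cols <- function(m, k) {
  # convolve each row (x direction); k has odd length
  half <- (length(k) - 1L) / 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  for (j in seq_along(k)) {
    off <- j - 1L - half
    idx <- pmin(pmax(seq_len(nc) + off, 1L), nc)
    out <- out + k[j] * m[, idx, drop = FALSE]
  }
  out
}

.conv_along_rows <- function(m, k) {
  half <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k)) {
    off <- j - 1L - half
    idx <- pmin(pmax(seq_len(nr) + off, 1L), nr)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  out
}

.gauss_kernels <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  list(g = g, dg = dg)
}

# shift a matrix by (dr, dc), zero padding
.shift0 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

#' Canny edge detection with automatic hysteresis thresholds
#'
#' Gradients of the luminance plane (the L channel of the CIELAB conversion,
#' or a numeric matrix supplied directly) are computed with
#' derivative-of-Gaussian filters of width \code{sigma}, followed by
#' non-maximum suppression perpendicular to the edge and hysteresis linking.
#' The hysteresis thresholds are \code{low_rate} and \code{high_rate} times
#' the Otsu threshold of the gradient-magnitude distribution (computed on the
#' max-normalized 256-bin histogram and mapped back), which makes the edge
#' map invariant to affine rescaling of the luminance and robust on images
#' where structure is sparse relative to background noise. When the reference
#' does not stand clear of the noise floor (less than 4 times the median
#' gradient magnitude, beyond the reach of Rayleigh-distributed pure noise)
#' the image is considered structureless and no edges are returned.
#'
#' @param img an \code{ihc_image}, or a numeric matrix used directly as the
#'   luminance plane.
#' @param params an \code{\link{eda_params}} list.
#' @return Binary edge map (0/255).
#' @export
auto_canny <- function(img, params = eda_params()) {
  lum <- if (inherits(img, "ihc_image")) {
    matrix(as.numeric(rgb_to_lab(img)$L), image_height(img), image_width(img))
  } else {
    m <- as.matrix(img)
    storage.mode(m) <- "double"
    m
  }
  k <- .gauss_kernels(params$sigma)
  # x-derivative: smooth along rows (y), differentiate along columns (x)
  gx <- .conv_along_cols(.conv_along_rows(lum, k$g), k$dg)
  gy <- .conv_along_rows(.conv_along_cols(lum, k$g), k$dg)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  out <- matrix(0L, nrow(lum), ncol(lum))
  if (mmax <= 1e-9 * max(max(lum) - min(lum), 1e-12)) return(out)
  # non-maximum suppression: quantize gradient direction into 4 sectors
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- ifelse(ang < pi / 8 | ang >= 7 * pi / 8, 0L,
            ifelse(ang < 3 * pi / 8, 1L,
            ifelse(ang < 5 * pi / 8, 2L, 3L)))
  # neighbour offsets (dy, dx) along the gradient for each sector
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  keep <- matrix(FALSE, nrow(lum), ncol(lum))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    n1 <- .shift0(mag, o[1], o[2])
    n2 <- .shift0(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag > n1 & mag >= n2)
  }
  ref <- EBImage::otsu(EBImage::Image(mag / mmax), range = c(0, 1),
                       levels = 256L) * mmax
  # noise-floor guard: for pure sensor noise the gradient magnitude is
  # Rayleigh-distributed, whose 99.9th percentile is ~3.2x its median, so a
  # reference below 4 medians cannot mark structure; return no edges
  if (ref < 4 * stats::median(mag)) return(out)
  weak <- keep & mag >= params$low_rate * ref
  strong <- keep & mag >= params$high_rate * ref
  if (!any(strong)) return(out)
  lab <- .cc_label8(matrix(as.integer(weak), nrow(lum), ncol(lum)))
  good <- unique(lab[strong])
  good <- good[good > 0L]
  out[lab %in% good] <- 255L
  out
}

#' Convert closed edge regions to cell points
#'
#' Closes the edge map morphologically (3x3 square), fills the fully
#' enclosed interiors, drops connected components that enclose no interior
#' (open arcs and dangling edge fragments), and extracts cells from the
#' remaining filled regions with the diameter filter.
#'
#' @param edges binary edge map (0/255).
#' @param rng a \code{\link{diameter_range}} in pixels.
#' @return A cells data frame with source \code{"EDA"}.
#' @export
edges_to_cells <- function(edges, rng) {
  if (!any(edges == 255L)) return(cells_df())
  closed <- EBImage::closing(.as_ebimage_binary(edges),
                             EBImage::makeBrush(3L, shape = "box"))@.Data > 0.5
  filled <- EBImage::fillHull(EBImage::Image(closed * 1))@.Data > 0.5
  interior <- filled & !closed
  lab <- .cc_label8(matrix(as.integer(filled), nrow(edges), ncol(edges)))
  enclosing <- unique(lab[interior])
  enclosing <- enclosing[enclosing > 0L]
  if (length(enclosing) == 0L) return(cells_df())
  mask <- matrix(0L, nrow(edges), ncol(edges))
  mask[lab %in% enclosing] <- 255L
  extract_cells(mask, rng, source = "EDA")
}

#' Edge-based cell detection
#'
#' @param img an \code{ihc_image}.
#' @param rng a \code{\link{diameter_range}} in pixels.
#' @param params an \code{\link{eda_params}} list.
#' @return A cells data frame with source \code{"EDA"}.
#' @export
eda_detect <- function(img, rng, params = eda_params()) {
  edges_to_cells(auto_canny(img, params), rng)
}
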