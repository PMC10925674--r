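# Deterministic generator of IHC-like scenes with ground truth: brown nuclei
# at two staining intensities plus bluish unstained nuclei on a pale
# background, rendered as noisy filled ellipses.

#' Parameters of the synthetic scene generator
#'
#' Defaults emulate a DAB/hematoxylin field at moderate magnification:
#' strongly stained nuclei are dark brown, weakly stained nuclei light brown,
#' unstained nuclei blue-purple (counterstain) and the background pale. The
#' palette is chosen so that the L*b grey projection used by the
#' region-based detector is lowest over stain and highest over background.
#'
#' @param size image side in pixels (square scene, default 512).
#' @param n_high,n_low,n_none nuclei counts per category (default 10 each).
#' @param d_min,d_max nucleus diameter range in pixels (default 14-26).
#' @param col_high,col_low,col_none,col_bg mean RGB colours.
#' @param col_sd per-channel Gaussian noise standard deviation (default 8).
#' @param spacing minimum distance between nucleus centres (default
#'   \code{1.2 * d_max}).
#' @param blotch_rate expected number of faint background blotches
#'   (default 0).
#' @param seed RNG seed; scenes are bit-identical for equal parameters.
#' @return Named list of parameters.
#' @export
synth_params <- function(size = 512L, n_high = 10L, n_low = 10L, n_none = 10L,
                         d_min = 14, d_max = 26,
                         col_high = c(90, 60, 30), col_low = c(170, 130, 90),
                         col_none = c(150, 150, 200),
                         col_bg = c(235, 230, 238),
                         col_sd = 8, spacing = 1.2 * d_max,
                         blotch_rate = 0, seed = 1L) {
  stopifnot(size >= 32L, n_high >= 0L, n_low >= 0L, n_none >= 0L,
            d_min > 0, d_min < d_max, spacing > 0, col_sd >= 0)
  cols <- rbind(HIGH = col_high, LOW = col_low, NONE = col_none, BG = col_bg)
  if (any(cols < 0 | cols > 255)) stop("colours must be in [0, 255]")
  list(size = as.integer(size), n_high = as.integer(n_high),
       n_low = as.integer(n_low), n_none = as.integer(n_none),
       d_min = d_min, d_max = d_max, colors = cols, col_sd = col_sd,
       spacing = spacing, blotch_rate = blotch_rate, seed = as.integer(seed))
}

.clip255 <- function(m) pmin(255, pmax(0, m))

# paint one noisy filled ellipse into the 3-channel numeric array
.paint_ellipse <- function(arr, cx, cy, a, b, theta, col, col_sd) {
  size_y <- dim(arr)[1]; size_x <- dim(arr)[2]
  r <- max(a, b)
  xs <- max(0, floor(cx - r)):min(size_x - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(size_y - 1, ceiling(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  n_in <- sum(inside)
  if (n_in == 0) return(arr)
  ridx <- ys[row(inside)[inside]] + 1L
  cidx <- xs[col(inside)[inside]] + 1L
  for (ch in 1:3) {
    vals <- col[ch] + stats::rnorm(n_in, 0, col_sd)
    arr[cbind(ridx, cidx, ch)] <- .clip255(vals)
  }
  arr
}

# rejection-sample n centres with pairwise spacing inside the given box;
# existing centres are respected
.place_centres <- function(n, x_range, y_range, spacing, existing = NULL,
                           max_attempts = 10000L) {
  pts <- existing
  out <- matrix(NA_real_, n, 2L)
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " nuclei at the requested spacing; ",
           "reduce the counts or the spacing")
    cand <- c(stats::runif(1, x_range[1], x_range[2]),
              stats::runif(1, y_range[1], y_range[2]))
    if (!is.null(pts) && nrow(pts) > 0L &&
        any((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 < spacing^2))
      next
    placed <- placed + 1L
    out[placed, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

.render <- function(params, centres, categories) {
  size <- params$size
  arr <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3)
    arr[, , ch] <- .clip255(params$colors["BG", ch] +
                              stats::rnorm(size * size, 0, params$col_sd))
  n_blotch <- if (params$blotch_rate > 0) stats::rpois(1, params$blotch_rate) else 0L
  if (n_blotch > 0L) {
    blotch_col <- (params$colors["BG", ] + params$colors["LOW", ]) / 2
    for (i in seq_len(n_blotch)) {
      bc <- stats::runif(2, 0, size - 1)
      br <- stats::runif(1, params$d_max, 3 * params$d_max)
      arr <- .paint_ellipse(arr, bc[1], bc[2], br, br * stats::runif(1, 0.6, 1),
                            stats::runif(1, 0, pi), blotch_col, params$col_sd)
    }
  }
  n <- nrow(centres)
  diam <- stats::runif(n, params$d_min, params$d_max)
  ratio <- stats::runif(n, 0.8, 1.0)
  theta <- stats::runif(n, 0, pi)
  for (i in seq_len(n)) {
    a <- diam[i] / 2
    arr <- .paint_ellipse(arr, centres[i, 1], centres[i, 2], a, a * ratio[i],
                          theta[i], params$colors[categories[i], ], params$col_sd)
  }
  ihc_image(round(arr), id = sprintf("synthetic_seed%d", params$seed))
}

#' Render a synthetic IHC scene with ground truth
#'
#' Nucleus centres are rejection-sampled with a minimum spacing, then drawn
#' as filled ellipses (axis ratio 0.8-1, random orientation) with per-pixel
#' Gaussian colour noise over a noisy pale background. Fully deterministic
#' for a fixed seed.
#'
#' @param params a \code{\link{synth_params}} list.
#' @return List with \code{image} (an \code{ihc_image}) and \code{truth}
#'   (cells data frame with categories).
#' @export
render_scene <- function(params = synth_params()) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(params$seed)
  margin <- params$d_max / 2 + 2
  n <- c(params$n_high, params$n_low, params$n_none)
  categories <- rep(c("HIGH", "LOW", "NONE"), n)
  centres <- .place_centres(sum(n), c(margin, params$size - 1 - margin),
                            c(margin, params$size - 1 - margin),
                            params$spacing)
  img <- .render(params, centres, categories)
  truth <- cells_df(centres[, 1], centres[, 2], categories, "MANUAL")
  list(image = img, truth = truth)
}

#' Render a rotated epithelium band scene for strata testing
#'
#' A rectangular "epithelium" band, rotated by \code{rotation} degrees, is
#' used as the analysis region; the basal point is placed outside the band
#' beyond one long side. Nuclei are placed in the known thirds of the band
#' thickness (counted from the basal side), keeping their centres at least
#' \code{third_margin} pixels away from the third boundaries, and the
#' generating layer of every nucleus is recorded in the ground truth.
#'
#' @param params a \code{\link{synth_params}} list.
#' @param rotation band rotation in degrees (default 0).
#' @param n_per_third nuclei per layer (categories cycle HIGH/LOW/NONE;
#'   default 10).
#' @param band_length,band_thickness band dimensions in pixels.
#' @param third_margin minimal distance of a centre from a third boundary.
#' @return List with \code{image}, \code{region} (4 x 2 polygon),
#'   \code{basal} (point outside the band) and \code{truth} (cells with
#'   \code{category} and \code{layer} columns).
#' @export
epithelium_roi_scene <- function(params = synth_params(), rotation = 0,
                                 n_per_third = 10L,
                                 band_length = 0.75 * params$size,
                                 band_thickness = 0.45 * params$size,
                                 third_margin = 3) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(params$seed)
  size <- params$size
  c0 <- c(size - 1, size - 1) / 2
  th <- rotation * pi / 180
  u <- c(cos(th), sin(th))          # along band length
  v <- c(-sin(th), cos(th))         # across thickness, away from basal side
  half_l <- band_length / 2
  # basal side at offset -thickness/2 along v
  corner <- function(su, sv) c0 + su * half_l * u + sv * (band_thickness / 2) * v
  region <- rbind(corner(-1, -1), corner(1, -1), corner(1, 1), corner(-1, 1))
  colnames(region) <- c("x", "y")
  if (any(region < 2 | region > size - 3))
    stop("band does not fit in the image; reduce its dimensions")
  basal <- c0 - (band_thickness / 2 + 0.1 * size) * v
  third <- band_thickness / 3
  margin_u <- params$d_max / 2 + 2
  layers <- c("basal", "medial", "superior")
  uv <- NULL; layer_lab <- character(0)
  for (k in 1:3) {
    placed <- .place_centres(n_per_third,
                             c(-half_l + margin_u, half_l - margin_u),
                             c((k - 1) * third + third_margin,
                               k * third - third_margin),
                             params$spacing, existing = uv)
    uv <- rbind(uv, placed)
    layer_lab <- c(layer_lab, rep(layers[k], n_per_third))
  }
  # map (u, v-from-basal-side) to image coordinates
  centres <- t(apply(uv, 1, function(p)
    c0 + p[1] * u + (p[2] - band_thickness / 2) * v))
  categories <- rep_len(c("HIGH", "LOW", "NONE"), nrow(centres))
  img <- .render(params, centres, categories)
  truth <- cells_df(centres[, 1], centres[, 2], categories, "MANUAL")
  truth$layer <- layer_lab
  list(image = img, region = region, basal = basal, truth = truth)
}

#' Write / read a ground-truth table as CSV
#'
#' Columns \code{x, y, category, layer} (layer may be empty).
#'
#' @param truth cells data frame, optionally with a \code{layer} column.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(x = .fmt_coord(truth$x), y = .fmt_coord(truth$y),
                   category = truth$category,
                   layer = if ("layer" %in% names(truth)) truth$layer else "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(x = "numeric", y = "numeric",
                                       category = "character",
                                       layer = "character"))
  out <- cells_df(df$x, df$y, df$category, "MANUAL")
  if (any(nzchar(df$layer))) out$layer <- df$layer
  out
}
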