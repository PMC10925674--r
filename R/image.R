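#' RGB image container
#'
#' Lightweight container for an 8-bit RGB microscopy image. Pixels are stored
#' as an integer array of dimension \code{c(height, width, 3)} with values in
#' \code{[0, 255]}. Coordinates used throughout the package are 0-based with
#' the origin at the top-left corner, x growing rightward (columns) and y
#' growing downward (rows); pixel centres sit at integer coordinates.
#'
#' @param pixels numeric or integer array \code{[height, width, 3]} with
#'   values in \code{[0, 255]}.
#' @param id character identifier (typically the file path).
#' @return An object of class \code{ihc_image}.
#' @export
ihc_image <- function(pixels, id = "image") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must be at least 1 x 1")
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("channel values must be integers in [0, 255]")
  structure(list(pixels = px, id = as.character(id)[1]),
            class = "ihc_image")
}

#' @export
print.ihc_image <- function(x, ...) {
  cat(sprintf("<ihc_image> %s: %d x %d px, 8-bit RGB\n",
              x$id, image_width(x), image_height(x)))
  invisible(x)
}

#' @rdname ihc_image
#' @param img an \code{ihc_image}.
#' @export
image_width <- function(img) dim(img$pixels)[2]

#' @rdname ihc_image
#' @export
image_height <- function(img) dim(img$pixels)[1]

#' Read an 8-bit RGB image from PNG or TIFF
#'
#' @param path file path; the format is chosen from the file extension
#'   (\code{.png}, \code{.tif}, \code{.tiff}).
#' @return An \code{ihc_image}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  ihc_image(round(raw * 255), id = path)
}

#' Write an image to PNG or TIFF
#'
#' @param img an \code{ihc_image}.
#' @param path destination path (\code{.png}, \code{.tif} or \code{.tiff}).
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "ihc_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Convert an RGB image to 8-bit encoded CIELAB
#'
#' Converts sRGB pixels (D65 white point) to CIELAB and re-encodes each
#' channel on 8 bits: L* (range 0-100) is rescaled to \code{[0, 255]}, while
#' a* and b* are offset by +128 and clipped to \code{[0, 255]}. This encoding
#' keeps all channels non-negative, which the grey projection
#' \code{\link{grey_from_lab}} relies on (it multiplies L by b).
#'
#' @param img an \code{ihc_image}.
#' @return An object of class \code{lab_image}: a list of integer matrices
#'   \code{L}, \code{a}, \code{b} of the image dimensions.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(inherits(img, "ihc_image"))
  h <- image_height(img); w <- image_width(img)
  m <- matrix(as.numeric(img$pixels), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  enc <- function(v) {
    v <- as.integer(round(v))
    matrix(pmin(255L, pmax(0L, v)), nrow = h, ncol = w)
  }
  structure(list(L = enc(lab[, 1] * 255 / 100),
                 a = enc(lab[, 2] + 128),
                 b = enc(lab[, 3] + 128)),
            class = "lab_image")
}

#' Grey projection of a Lab image: normalized L*b product
#'
#' Multiplies the (8-bit encoded) L and b planes pixel-wise and min-max
#' normalizes the product to \code{[0, 255]}. In DAB-stained images the
#' product is lowest over strongly stained (dark, brown) nuclei and highest
#' over the pale background, so thresholding it from below isolates stain.
#' A constant product (e.g. a flat image) maps to all zeros.
#'
#' @param lab a \code{lab_image}.
#' @return Integer matrix in \code{[0, 255]}.
#' @export
grey_from_lab <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  prod <- as.numeric(lab$L) * as.numeric(lab$b)
  m <- min(prod); M <- max(prod)
  if (M == m) {
    out <- matrix(0L, nrow(lab$L), ncol(lab$L))
  } else {
    out <- matrix(as.integer(round(255 * (prod - m) / (M - m))),
                  nrow(lab$L), ncol(lab$L))
  }
  out
}

#' Convert a pixel measurement to physical units
#'
#' @param value_px non-negative value in pixels.
#' @param cal microns per pixel (positive number), or \code{NULL}/\code{NA}
#'   to keep pixel units.
#' @return \code{value_px * cal} when a calibration is set, \code{value_px}
#'   unchanged otherwise.
#' @export
to_physical <- function(value_px, cal = NULL) {
  stopifnot(all(value_px >= 0))
  if (is.null(cal) || length(cal) == 0L || is.na(cal)) return(value_px)
  if (cal <= 0) stop("calibration must be > 0 microns/pixel")
  value_px * cal
}
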