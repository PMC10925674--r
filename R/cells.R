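#' Cell point sets
#'
#' Detected cells are represented as a data frame with columns \code{x},
#' \code{y} (0-based sub-pixel image coordinates, origin top-left),
#' \code{category} (\code{"HIGH"}, \code{"LOW"}, \code{"NONE"} or \code{NA}
#' when not yet classified) and \code{source} (which detector produced the
#' point: \code{"RDA_HIGH"}, \code{"RDA_LOW"}, \code{"RDA_WS"}, \code{"EDA"}
#' or \code{"MANUAL"}).
#'
#' @param x,y numeric coordinate vectors.
#' @param category character vector or \code{NA}.
#' @param source character vector of detector tags.
#' @return A \code{data.frame} of cells.
#' @export
cells_df <- function(x = numeric(), y = numeric(),
                     category = NA_character_, source = "MANUAL") {
  n <- length(x)
  stopifnot(length(y) == n)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   category = rep_len(as.character(category), max(n, 0L))[seq_len(n)],
                   source = rep_len(as.character(source), max(n, 0L))[seq_len(n)],
                   stringsAsFactors = FALSE)
  bad_cat <- !is.na(df$category) & !df$category %in% c("HIGH", "LOW", "NONE")
  if (any(bad_cat)) stop("unknown stain category: ",
                         paste(unique(df$category[bad_cat]), collapse = ", "))
  bad_src <- !df$source %in% c("RDA_HIGH", "RDA_LOW", "RDA_WS", "EDA", "MANUAL")
  if (any(bad_src)) stop("unknown cell source: ",
                         paste(unique(df$source[bad_src]), collapse = ", "))
  df
}

# stain categories in canonical order; NONE is the negative class
.stain_levels <- c("HIGH", "LOW", "NONE")

#' Diameter range accepted by the detectors
#'
#' @param d_min,d_max strict lower and upper bounds on the equivalent-circle
#'   diameter of a detected region, in pixels (convert from microns with the
#'   calibration before calling).
#' @return A validated numeric vector \code{c(d_min, d_max)}.
#' @export
diameter_range <- function(d_min, d_max) {
  if (!(d_min > 0 && d_min < d_max))
    stop("diameter range requires 0 < d_min < d_max")
  c(d_min = as.numeric(d_min), d_max = as.numeric(d_max))
}
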