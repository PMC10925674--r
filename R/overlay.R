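# Overlay: the persisted analysis state of one image (region, basal point,
# calibration, diameters and cells), serialized to a versioned XML schema.

#' Create an analysis overlay
#'
#' An overlay bundles everything the analysis of one image produces: the
#' image identity and size, the spatial calibration, the cell diameter range,
#' the analysis region, the optional basal point (marking which side of the
#' region faces the basement membrane) and the detected/labelled cells. It is
#' the unit of persistence (one XML file per image).
#'
#' @param image_id character identifier of the image.
#' @param width,height image dimensions in pixels.
#' @param region analysis polygon (n x 2 matrix of >= 3 vertices, simple,
#'   implicitly closed).
#' @param cells a cells data frame (see \code{\link{cells_df}}); all cells
#'   must lie inside the region.
#' @param diameters a \code{\link{diameter_range}} in pixels.
#' @param calibration microns per pixel, or \code{NULL} for pixel units.
#' @param basal optional \code{c(x, y)} basal point, strictly outside the
#'   region.
#' @return An object of class \code{ihc_overlay}.
#' @export
overlay <- function(image_id, width, height, region, cells = cells_df(),
                    diameters = diameter_range(10, 40), calibration = NULL,
                    basal = NULL) {
  reg <- .validate_region(region)
  if (!is.null(calibration)) {
    if (!is.numeric(calibration) || length(calibration) != 1L || calibration <= 0)
      stop("calibration must be a positive scalar (microns/pixel) or NULL")
    calibration <- as.numeric(calibration)
  }
  diameters <- diameter_range(diameters[[1]], diameters[[2]])
  if (!is.null(basal)) {
    basal <- as.numeric(basal)
    if (length(basal) != 2L || anyNA(basal))
      stop("basal point must be c(x, y)")
    if (point_in_polygon(basal[1], basal[2], reg))
      stop("basal point must lie strictly outside the analysis region")
  }
  if (nrow(cells) > 0L) {
    if (any(cells$x < 0 | cells$x >= width | cells$y < 0 | cells$y >= height))
      stop("cells must lie inside the image bounds")
    inside <- point_in_polygon(cells$x, cells$y, reg)
    if (!all(inside))
      stop(sum(!inside), " cell(s) lie outside the analysis region")
  }
  structure(list(image_id = as.character(image_id)[1],
                 width = as.integer(width), height = as.integer(height),
                 calibration = calibration, diameters = diameters,
                 region = reg, basal = basal, cells = cells),
            class = "ihc_overlay")
}

#' @export
print.ihc_overlay <- function(x, ...) {
  cat(sprintf("<ihc_overlay> %s (%d x %d): %d region vertices, %d cells%s\n",
              x$image_id, x$width, x$height, nrow(x$region), nrow(x$cells),
              if (is.null(x$basal)) "" else ", basal point set"))
  invisible(x)
}

.fmt_coord <- function(v) sprintf("%.17g", v)

#' Write an overlay to XML
#'
#' The schema is versioned (root attribute \code{version="1"}); coordinates
#' are serialized with 10 significant digits so that a write/read round trip
#' is the identity on all fields.
#'
#' @param ov an \code{ihc_overlay}.
#' @param path destination file path.
#' @export
write_overlay <- function(ov, path) {
  stopifnot(inherits(ov, "ihc_overlay"))
  doc <- xml2::xml_new_root("overlay", version = "1")
  xml2::xml_add_child(doc, "image", id = ov$image_id,
                      width = as.character(ov$width),
                      height = as.character(ov$height))
  if (!is.null(ov$calibration))
    xml2::xml_add_child(doc, "calibration",
                        microns_per_pixel = .fmt_coord(ov$calibration))
  xml2::xml_add_child(doc, "diameters",
                      min = .fmt_coord(ov$diameters[["d_min"]]),
                      max = .fmt_coord(ov$diameters[["d_max"]]))
  reg <- xml2::xml_add_child(doc, "region")
  for (i in seq_len(nrow(ov$region)))
    xml2::xml_add_child(reg, "pt", x = .fmt_coord(ov$region[i, 1]),
                        y = .fmt_coord(ov$region[i, 2]))
  if (!is.null(ov$basal))
    xml2::xml_add_child(doc, "basal", x = .fmt_coord(ov$basal[1]),
                        y = .fmt_coord(ov$basal[2]))
  cells <- xml2::xml_add_child(doc, "cells")
  for (i in seq_len(nrow(ov$cells))) {
    attrs <- list(x = .fmt_coord(ov$cells$x[i]), y = .fmt_coord(ov$cells$y[i]),
                  source = ov$cells$source[i])
    if (!is.na(ov$cells$category[i])) attrs$category <- ov$cells$category[i]
    do.call(xml2::xml_add_child, c(list(cells, "cell"), attrs))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.req_attr <- function(node, attr, what) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) stop("overlay XML: missing attribute '", attr, "' on <", what, ">")
  v
}

#' Read an overlay from XML
#'
#' @param path path to a file written by \code{\link{write_overlay}} (or
#'   hand-written to the same schema). Parsed overlays are re-validated
#'   against all type invariants; violations raise an error naming the
#'   offending element.
#' @return An \code{ihc_overlay}.
#' @export
read_overlay <- function(path) {
  if (!file.exists(path)) stop("overlay file not found: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "overlay")
    stop("overlay XML: root element must be <overlay>")
  ver <- xml2::xml_attr(doc, "version")
  if (is.na(ver) || ver != "1")
    stop("overlay XML: unknown schema version '", ver, "'")
  img <- xml2::xml_find_first(doc, "./image")
  if (inherits(img, "xml_missing")) stop("overlay XML: missing <image>")
  cal_node <- xml2::xml_find_first(doc, "./calibration")
  cal <- if (inherits(cal_node, "xml_missing")) NULL else
    as.numeric(.req_attr(cal_node, "microns_per_pixel", "calibration"))
  dia <- xml2::xml_find_first(doc, "./diameters")
  if (inherits(dia, "xml_missing")) stop("overlay XML: missing <diameters>")
  pts <- xml2::xml_find_all(doc, "./region/pt")
  if (length(pts) < 3L) stop("overlay XML: <region> needs at least 3 <pt>")
  region <- cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
                  y = as.numeric(xml2::xml_attr(pts, "y")))
  basal_node <- xml2::xml_find_first(doc, "./basal")
  basal <- if (inherits(basal_node, "xml_missing")) NULL else
    c(as.numeric(.req_attr(basal_node, "x", "basal")),
      as.numeric(.req_attr(basal_node, "y", "basal")))
  cell_nodes <- xml2::xml_find_all(doc, "./cells/cell")
  cells <- if (length(cell_nodes) == 0L) cells_df() else {
    cat <- xml2::xml_attr(cell_nodes, "category")
    cells_df(x = as.numeric(xml2::xml_attr(cell_nodes, "x")),
             y = as.numeric(xml2::xml_attr(cell_nodes, "y")),
             category = cat,
             source = xml2::xml_attr(cell_nodes, "source"))
  }
  overlay(image_id = .req_attr(img, "id", "image"),
          width = as.integer(.req_attr(img, "width", "image")),
          height = as.integer(.req_attr(img, "height", "image")),
          region = region, cells = cells,
          diameters = c(as.numeric(.req_attr(dia, "min", "diameters")),
                        as.numeric(.req_attr(dia, "max", "diameters"))),
          calibration = cal, basal = basal)
}
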