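#' Axis-aligned bounding boxes
#'
#' Boxes use a 0-based, half-open pixel convention: a box `(x, y, w, h)`
#' covers image columns `x+1 .. x+w` and rows `y+1 .. y+h` in R's 1-based
#' matrix indexing, so `w` and `h` are true pixel extents and the box area is
#' `w * h`. `bbox()` builds a single box; most metric functions also accept a
#' data frame with columns `x`, `y`, `w`, `h` (one box per row) so that large
#' batches of boxes stay tabular and pipe-friendly.
#'
#' @param x,y Left/top corner, 0-based pixels.
#' @param w,h Width and height in pixels; must be positive.
#' @return An object of class `bbox` (a named list).
#' @examples
#' b <- bbox(10, 20, 100, 50)
#' bbox_area(b)
#' @export
bbox <- function(x, y, w, h) {
  if (any(!is.finite(c(x, y, w, h)))) abort("bbox coordinates must be finite")
  if (w <= 0 || h <= 0) abort("bbox width and height must be positive")
  structure(list(x = x, y = y, w = w, h = h), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' @export
format.bbox <- function(x, ...) sprintf("(%g,%g,%g,%g)", x$x, x$y, x$w, x$h)

#' Coerce boxes to a one-row-per-box tibble
#'
#' @param boxes A `bbox`, a list of `bbox` objects, or a data frame already
#'   holding columns `x`, `y`, `w`, `h`.
#' @return A tibble with columns `x`, `y`, `w`, `h`.
#' @export
bbox_tbl <- function(boxes) {
  if (inherits(boxes, "bbox")) boxes <- list(boxes)
  if (is.data.frame(boxes)) {
    stopifnot(all(c("x", "y", "w", "h") %in% names(boxes)))
    return(as_tibble(boxes[, c("x", "y", "w", "h"), drop = FALSE]))
  }
  tibble(
    x = vapply(boxes, `[[`, numeric(1), "x"),
    y = vapply(boxes, `[[`, numeric(1), "y"),
    w = vapply(boxes, `[[`, numeric(1), "w"),
    h = vapply(boxes, `[[`, numeric(1), "h")
  )
}

#' @rdname bbox
#' @param box A `bbox`.
#' @export
bbox_area <- function(box) box$w * box$h

#' Tight bounding box of a binary mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @return A `bbox` covering exactly the rows/columns containing `TRUE`.
#' @export
bbox_from_mask <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask is empty: no bounding box exists")
  r <- range(idx[, 1]); c <- range(idx[, 2])
  bbox(x = c[1] - 1, y = r[1] - 1, w = c[2] - c[1] + 1, h = r[2] - r[1] + 1)
}

#' Clip a box to an image frame
#'
#' @param box A `bbox`.
#' @param dims Integer vector `c(height, width)` of the frame.
#' @return The clipped `bbox`; errors if the box lies fully outside the frame.
#' @export
bbox_clip <- function(box, dims) {
  x0 <- max(box$x, 0); y0 <- max(box$y, 0)
  x1 <- min(box$x + box$w, dims[2]); y1 <- min(box$y + box$h, dims[1])
  if (x1 <= x0 || y1 <= y0) abort("box lies entirely outside the frame")
  bbox(x0, y0, x1 - x0, y1 - y0)
}

#' Rasterize a box as a binary mask
#'
#' A present box becomes a filled rectangle; `NULL` (no detection) falls back
#' to a whole-frame mask, the convention used when a detector finds nothing
#' and features must still be extracted from the image.
#'
#' @param box A `bbox`, a `detection`, or `NULL`.
#' @param dims `c(height, width)` of the frame.
#' @return A logical matrix of size `dims`.
#' @export
box_to_mask <- function(box, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (is.null(box)) {
    m[] <- TRUE
    return(m)
  }
  if (inherits(box, "detection")) box <- box$box
  b <- box
  if (b$x < 0 || b$y < 0 || b$x + b$w > dims[2] || b$y + b$h > dims[1]) {
    warn("box extends outside the frame; clipping")
    b <- bbox_clip(b, dims)
  }
  rows <- (floor(b$y) + 1):ceiling(b$y + b$h)
  cols <- (floor(b$x) + 1):ceiling(b$x + b$w)
  m[rows, cols] <- TRUE
  m
}

#' Normalized box representation
#'
#' Center/size coordinates each divided by the matching image dimension, the
#' representation in which the localization error is computed.
#'
#' @param boxes Boxes acceptable to [bbox_tbl()].
#' @param dims `c(height, width)` of the frame.
#' @return Tibble with columns `xc`, `yc`, `w`, `h` in `[0, 1]` units.
#' @export
bbox_normalize <- function(boxes, dims) {
  if (is.null(dims) || length(dims) < 2) {
    abort("image dims are required to normalize box coordinates")
  }
  b <- bbox_tbl(boxes)
  tibble(
    xc = (b$x + b$w / 2) / dims[2],
    yc = (b$y + b$h / 2) / dims[1],
    w = b$w / dims[2],
    h = b$h / dims[1]
  )
}

# ---- Pascal VOC style XML annotations ---------------------------------------
# Dialect: the written <xmin>/<ymin> are the 0-based left/top corner and
# <xmax>/<ymax> the exclusive right/bottom corner, so w = xmax - xmin and
# h = ymax - ymin. Files written and read by this package round-trip exactly.

#' Write boxes of one image as a VOC-style XML annotation
#'
#' @param path Output file path.
#' @param image_id Image identifier stored in `<filename>`.
#' @param dims `c(height, width)` of the frame.
#' @param boxes Boxes acceptable to [bbox_tbl()]; may have zero rows.
#' @param label Object name to store (recycled), default "lesion".
#' @return `path`, invisibly.
#' @export
voc_write <- function(path, image_id, dims, boxes, label = "lesion") {
  b <- bbox_tbl(boxes)
  label <- rep_len(label, nrow(b))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", as.character(image_id))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(dims[2]))
  xml2::xml_add_child(size, "height", as.character(dims[1]))
  xml2::xml_add_child(size, "depth", "1")
  if (nrow(b) > 0) {
    for (i in seq_len(nrow(b))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", label[i])
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(b$x[i]))
      xml2::xml_add_child(bb, "ymin", as.character(b$y[i]))
      xml2::xml_add_child(bb, "xmax", as.character(b$x[i] + b$w[i]))
      xml2::xml_add_child(bb, "ymax", as.character(b$y[i] + b$h[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a VOC-style XML annotation
#'
#' @param path XML file written by [voc_write()] or following the same
#'   corner convention (see the package's format note in the vignette).
#' @return Tibble with columns `image_id`, `label`, `x`, `y`, `w`, `h`;
#'   zero rows if the file contains no objects.
#' @export
voc_read <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed VOC XML '%s': %s", path, conditionMessage(e)))
  })
  image_id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0) {
    return(tibble(image_id = character(), label = character(),
                  x = numeric(), y = numeric(), w = numeric(), h = numeric()))
  }
  num <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, paste0("./bndbox/", tag)))
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) {
      abort(sprintf("malformed VOC XML '%s': element <%s> is not numeric ('%s')",
                    path, tag, v))
    }
    out
  }
  purrr::map_dfr(objs, function(o) {
    xmin <- num(o, "xmin"); ymin <- num(o, "ymin")
    xmax <- num(o, "xmax"); ymax <- num(o, "ymax")
    if (xmax <= xmin || ymax <= ymin) {
      abort(sprintf("malformed VOC XML '%s': degenerate box [%g,%g,%g,%g]",
                    path, xmin, ymin, xmax, ymax))
    }
    tibble(
      image_id = image_id,
      label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
      x = xmin, y = ymin, w = xmax - xmin, h = ymax - ymin
    )
  })
}
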