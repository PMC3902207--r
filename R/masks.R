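#' Segmentation mask on the neuron grid
#'
#' @param mask Logical matrix (neuron-grid rows x columns).
#' @param label Label string.
#' @return A `segment_mask` with the area (number of true cells) attached.
#' @export
segment_mask <- function(mask, label = "") {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask != 0
  structure(list(mask = mask, label = label, area = sum(mask)),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment_mask '%s', %d cells on %dx%d grid>\n",
              x$label, x$area, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
# `px`, `py` numeric vectors (same length); `poly` a matrix with columns
# x, y in the same coordinate frame.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n < 3L) stop("polygons must have >= 3 vertices")
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterize a polygon given in image pixel coordinates (0-based, x right,
# y down) onto an nr x nc neuron grid with the given stride: grid cell
# (gy, gx) covers pixels [ (gx-1)*stride, gx*stride ) and is inside when
# its center pixel is inside the polygon.
rasterize_polygon <- function(poly, nr, nc, stride = 2L) {
  gx <- matrix(rep(seq_len(nc), each = nr), nr)
  gy <- matrix(rep(seq_len(nr), nc), nr)
  cx <- (gx - 0.5) * stride
  cy <- (gy - 0.5) * stride
  matrix(point_in_polygon(as.numeric(cx), as.numeric(cy), poly), nr, nc)
}

# Downsample an integer label raster at image resolution to per-label
# neuron-grid masks: a cell carries label L if any covered pixel does.
raster_to_masks <- function(labels, stride = 2L, names = NULL) {
  nr <- nrow(labels) %/% stride
  nc <- ncol(labels) %/% stride
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  lapply(ids, function(id) {
    hit <- labels[seq_len(nr * stride), seq_len(nc * stride)] == id
    cell <- matrix(FALSE, nr, nc)
    for (dr in seq_len(stride)) for (dc in seq_len(stride)) {
      cell <- cell | hit[seq(dr, by = stride, length.out = nr),
                         seq(dc, by = stride, length.out = nc)]
    }
    lab <- if (!is.null(names) && id <= length(names)) names[id]
           else as.character(id)
    segment_mask(cell, lab)
  })
}

#' Load segmentation masks
#'
#' Accepts (a) an integer label matrix at image resolution (0 =
#' background), (b) a path to a plain-text TSV label raster or a 16-bit
#' label PNG, or (c) a path to a LabelMe-style XML annotation with
#' `<object><polygon><pt><x><y>` entries. Polygons are scaled from the
#' original image size to the working size and rasterized onto the neuron
#' grid (image coordinates divided by `stride`). Overlapping masks are
#' preserved as-is.
#'
#' @param source Matrix or file path.
#' @param stride Neuron-grid stride (default 2).
#' @param target Working image size `c(height, width)` the polygons refer
#'   to after resizing (default `c(300, 400)`).
#' @param image_size Original image size `c(height, width)` for XML
#'   sources; taken from the `<imagesize>` element when present.
#' @param labels Optional character vector naming raster label ids.
#' @return List of [segment_mask()] objects.
#' @export
load_masks <- function(source, stride = 2L, target = c(300L, 400L),
                       image_size = NULL, labels = NULL) {
  if (is.matrix(source))
    return(raster_to_masks(source, stride, labels))
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("tsv", "txt")) {
    m <- as.matrix(read.delim(source, header = FALSE))
    storage.mode(m) <- "integer"
    return(raster_to_masks(m, stride, labels))
  }
  if (ext == "png") {
    m <- round(png::readPNG(source) * 65535)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    storage.mode(m) <- "integer"
    return(raster_to_masks(m, stride, labels))
  }
  if (ext == "xml") {
    doc <- xml2::read_xml(source)
    if (is.null(image_size)) {
      nrows <- xml2::xml_find_first(doc, ".//imagesize/nrows")
      ncols <- xml2::xml_find_first(doc, ".//imagesize/ncols")
      if (inherits(nrows, "xml_missing"))
        stop("XML has no <imagesize>; supply `image_size`")
      image_size <- c(as.numeric(xml2::xml_text(nrows)),
                      as.numeric(xml2::xml_text(ncols)))
    }
    sx <- target[2] / image_size[2] / stride
    sy <- target[1] / image_size[1] / stride
    nr <- target[1] %/% stride
    nc <- target[2] %/% stride
    objs <- xml2::xml_find_all(doc, ".//object")
    masks <- list()
    for (ob in objs) {
      pts <- xml2::xml_find_all(ob, ".//polygon/pt")
      if (length(pts) < 3L) stop("polygons must have >= 3 vertices")
      poly <- cbind(
        x = as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "x"))) * sx,
        y = as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "y"))) * sy)
      # here polygon coordinates are already on the neuron grid: stride 1
      cell <- rasterize_polygon(poly, nr, nc, stride = 1L)
      if (!any(cell)) stop("polygon entirely outside image")
      lab <- xml2::xml_text(xml2::xml_find_first(ob, ".//name"))
      masks[[length(masks) + 1L]] <- segment_mask(cell, lab)
    }
    return(masks)
  }
  stop("unsupported mask source: ", source)
}

#' Filter masks by evaluated segment size
#'
#' Keeps masks whose area on the neuron grid lies in
#' `[min_area, max_area]`; the defaults admit segments of at least the
#' forward-projection patch size (6 x 6 = 36 neurons) and at most half of
#' a 200 x 150 grid.
#'
#' @param masks List of [segment_mask()] objects.
#' @param min_area,max_area Inclusive area bounds in neuron-grid cells.
#' @return Filtered list.
#' @export
filter_masks <- function(masks, min_area = 36L, max_area = 15000L) {
  Filter(function(m) m$area >= min_area && m$area <= max_area, masks)
}
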