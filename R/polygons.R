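# Polygon rasterisation and ROI layout IO.
#
# Coordinate convention: polygons are given as n x 2 matrices of 0-based
# (row, col) coordinates; the center of image matrix element [i, j] sits at
# (row = i - 1, col = j - 1). Pixel membership uses the even-odd rule on
# pixel centers, with polygons closed implicitly.

#' Rasterise a polygon to a pixel mask
#'
#' Scanline even-odd rasterisation: a pixel belongs to the polygon when a
#' ray from its center in the +col direction crosses the polygon boundary
#' an odd number of times. Vertices are 0-based `(row, col)`; the polygon
#' is closed implicitly.
#'
#' @param nrow,ncol Image dimensions.
#' @param polygon Either an n x 2 vertex matrix or a list with a
#'   `vertices` element (n >= 3).
#' @return Logical `nrow x ncol` matrix.
#' @export
polygon_mask <- function(nrow, ncol, polygon) {
  v <- if (is.list(polygon) && !is.null(polygon$vertices)) {
    polygon$vertices
  } else polygon
  v <- as.matrix(v)
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices")
  if (any(v[, 1] < -0.5 | v[, 1] > nrow - 0.5 |
          v[, 2] < -0.5 | v[, 2] > ncol - 0.5)) {
    stop("polygon extends outside the image bounds")
  }
  ys <- v[, 1]; xs <- v[, 2]
  n <- nrow(v)
  y2 <- ys[c(2:n, 1)]; x2 <- xs[c(2:n, 1)]
  mask <- matrix(FALSE, nrow, ncol)
  xc <- 0:(ncol - 1)
  rmin <- max(1L, floor(min(ys)) + 1L)
  rmax <- min(nrow, ceiling(max(ys)) + 1L)
  for (i in rmin:rmax) {
    y <- i - 1  # pixel-center row coordinate
    # half-open rule: edge crosses the scanline when y in [min, max)
    cross <- (ys <= y & y < y2) | (y2 <= y & y < ys)
    if (!any(cross)) next
    xint <- xs[cross] + (y - ys[cross]) * (x2[cross] - xs[cross]) /
      (y2[cross] - ys[cross])
    # pixel center inside iff an odd number of crossings lie strictly right
    counts <- colSums(outer(xint, xc, `>`))
    mask[i, ] <- counts %% 2L == 1L
  }
  mask
}

#' Build a schematic grid ROI layout
#'
#' Lays the named ROIs out as rectangles on a regular grid, one polygon
#' per ROI and hemisphere, for a given section. Rectangle corners sit at
#' half-integer coordinates so no pixel center ever lies exactly on an
#' edge. Schematic only -- no anatomical realism is attempted.
#'
#' @param roi_names Character vector of ROI names.
#' @param dims Image `c(nrow, ncol)`; must be large enough for the grid.
#' @param section Section index recorded in each polygon (default 1).
#' @param hemispheres Hemisphere labels to lay out (default `c("L", "R")`;
#'   the two hemispheres occupy the left and right image halves).
#' @param cell Rectangle edge length in pixels (default 12).
#' @param margin Outer margin in pixels kept clear for background/blank
#'   regions (default 8).
#' @return List of polygon lists (`roi`, `hemisphere`, `section`,
#'   `vertices`).
#' @export
make_roi_layout <- function(roi_names, dims = c(160, 320), section = 1L,
                            hemispheres = c("L", "R"), cell = 12,
                            margin = 8) {
  n <- length(roi_names)
  half_w <- if (length(hemispheres) == 2) dims[2] / 2 else dims[2]
  ncell <- floor((half_w - 2 * margin) / cell)
  nrowc <- floor((dims[1] - 2 * margin) / cell)
  if (ncell * nrowc < n) {
    stop("image dims too small for ", n, " ROIs at cell size ", cell)
  }
  out <- list()
  for (h in seq_along(hemispheres)) {
    x0 <- margin + (h - 1) * half_w
    for (k in seq_len(n)) {
      r <- (k - 1) %/% ncell
      c0 <- (k - 1) %% ncell
      top <- margin + r * cell + 0.5
      left <- x0 + c0 * cell + 0.5
      # inset by 1px so neighbouring ROIs never share an edge
      vert <- rbind(c(top, left), c(top, left + cell - 2),
                    c(top + cell - 2, left + cell - 2),
                    c(top + cell - 2, left))
      out[[length(out) + 1L]] <- list(roi = roi_names[k],
                                      hemisphere = hemispheres[h],
                                      section = as.integer(section),
                                      vertices = vert)
    }
  }
  out
}

#' Write / read an ROI layout as JSON
#'
#' Serialises a list of polygons (`roi`, `hemisphere`, `section`,
#' 0-based `(row, col)` `vertices`) to JSON and back.
#'
#' @param layout List of polygon lists.
#' @param path File path.
#' @return `write_roi_layout` returns `path` invisibly; `read_roi_layout`
#'   the layout list.
#' @export
write_roi_layout <- function(layout, path) {
  payload <- lapply(layout, function(p) {
    list(roi = p$roi, hemisphere = p$hemisphere, section = p$section,
         vertices = unname(apply(p$vertices, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_layout
#' @export
read_roi_layout <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    list(roi = p$roi, hemisphere = p$hemisphere,
         section = as.integer(p$section),
         vertices = do.call(rbind, lapply(p$vertices, unlist)))
  })
}

#' Write / read an 8-bit grayscale image (PNG or TIFF)
#'
#' Gray levels are integers in `[0, 255]`, stored as a matrix. The format
#' is chosen from the file extension.
#'
#' @param image Integer/numeric matrix of gray levels in `[0, 255]`.
#' @param path Destination ending in `.png` or `.tif(f)`.
#' @return `write_gray_image` returns `path` invisibly; `read_gray_image`
#'   a gray-level matrix in `[0, 255]`.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(all(image >= 0 & image <= 255))
  norm <- image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    out <- tiff::readTIFF(path)
    if (is.list(out)) out[[1]] else out
  } else {
    stop("unsupported image extension: ", ext)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}
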