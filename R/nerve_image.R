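#' Nerve cross-section image container
#'
#' Bundles an 8-bit RGB raster with its physical pixel size and an optional
#' region-of-interest polygon. This is the substrate for [detect_axons()].
#' Pixel coordinates follow R's convention: `(row, col)`, 1-based, with pixel
#' centers at integer coordinates. Areas are computed by pixel counting and
#' converted to square microns via `pixel_size_um^2`.
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 255]`.
#' @param pixel_size_um physical size of one pixel in microns (> 0).
#' @param roi optional two-column matrix of `(row, col)` polygon vertices.
#'   `NULL` means the whole frame.
#' @return an object of class `nerve_image`.
#' @export
nerve_image <- function(pixels, pixel_size_um = 0.23, roi = NULL) {
  assert_that(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
              "pixels must be a height x width x 3 array")
  assert_that(min(pixels) >= 0 && max(pixels) <= 255,
              "pixel values must lie in [0, 255]")
  assert_that(is.numeric(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be > 0")
  if (!is.null(roi)) {
    roi <- matrix(as.numeric(roi), ncol = 2)
    assert_that(nrow(roi) >= 3, "roi polygon needs at least 3 vertices")
    d <- dim(pixels)
    assert_that(all(roi[, 1] >= 1 & roi[, 1] <= d[1] &
                    roi[, 2] >= 1 & roi[, 2] <= d[2]),
                "roi vertices must lie inside the image frame")
    assert_that(polygon_area(roi) > 0, "roi polygon must have positive area")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, roi = roi),
            class = "nerve_image")
}

#' @export
print.nerve_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("nerve_image: %d x %d px RGB, %.3g um/px%s\n",
              d[1], d[2], x$pixel_size_um,
              if (is.null(x$roi)) ", full-frame ROI"
              else sprintf(", ROI polygon with %d vertices", nrow(x$roi))))
  invisible(x)
}

#' ROI polygon area in mm^2
#'
#' @param image a [nerve_image()]. A `NULL` ROI means the full frame.
#' @return area of the ROI in square millimetres.
#' @export
roi_area_mm2 <- function(image) {
  d <- dim(image$pixels)
  area_px <- if (is.null(image$roi)) prod(d[1:2]) else polygon_area(image$roi)
  area_px * image$pixel_size_um^2 * 1e-6
}

#' Write / read a nerve image as 8-bit RGB TIFF (or PNG)
#'
#' Pixel size and ROI are not stored in the file; supply them again on read.
#'
#' @param image a [nerve_image()].
#' @param path file path; the extension selects the format.
#' @export
write_nerve_image <- function(image, path) {
  px <- round(image$pixels) / 255
  # EBImage images are indexed (x, y) = (col, row)
  img <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_nerve_image
#' @param pixel_size_um,roi as in [nerve_image()].
#' @export
read_nerve_image <- function(path, pixel_size_um = 0.23, roi = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  nerve_image(aperm(a * 255, c(2, 1, 3)), pixel_size_um = pixel_size_um,
              roi = roi)
}

#' Read an ROI polygon from CSV
#'
#' Expects columns `row` and `col` (pixel coordinates, one vertex per line).
#'
#' @param path CSV file path.
#' @return two-column matrix of vertices.
#' @export
read_roi_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("row", "col") %in% names(d)),
              "ROI CSV must have columns 'row' and 'col'")
  cbind(row = d$row, col = d$col)
}
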