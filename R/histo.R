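# DAB-positive area quantification. A pixel counts as DAB-positive when
# (R - G)/B >= threshold with R, G, B in [0, 1]; the default threshold is
# 0.5. Pixels with B = 0 are defined non-positive (division guard) and
# reported separately.

#' DAB-positive fraction inside a region of interest
#'
#' @param image height x width x 3 RGB array with channels in `[0, 1]`
#'   (see [read_rgb_image()]), or the list returned by
#'   [simulate_dab_image()].
#' @param roi logical matrix of the same height/width marking the region of
#'   interest; default the whole image.
#' @param threshold positivity threshold on `(R - G)/B` (default 0.5).
#' @param name ROI name recorded in the result (default `"roi"`).
#' @return A `roi_quant` data.frame row: `roi`, `positive_pixels`,
#'   `total_pixels`, `fraction`, `b_zero_pixels` (pixels skipped by the
#'   `B = 0` guard).
#' @export
dab_positive_fraction <- function(image, roi = NULL, threshold = 0.5,
                                  name = "roi") {
  if (is.list(image) && !is.null(image$image)) {
    if (is.null(roi)) roi <- image$roi
    image <- image$image
  }
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3)
    stop_param("image must be a height x width x 3 array")
  if (min(image) < 0 || max(image) > 1)
    stop_param("image channels must lie in [0, 1]")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  if (!identical(dim(roi), c(h, w)))
    stop_param("image and roi dimensions differ")
  roi <- roi & !is.na(roi)
  if (!any(roi)) stop_param("roi is empty")
  R <- image[, , 1][roi]
  G <- image[, , 2][roi]
  B <- image[, , 3][roi]
  bz <- B == 0
  pos <- !bz & (R - G) / ifelse(bz, 1, B) >= threshold
  out <- data.frame(roi = name, positive_pixels = sum(pos),
                    total_pixels = sum(roi),
                    fraction = sum(pos) / sum(roi),
                    b_zero_pixels = sum(bz), stringsAsFactors = FALSE)
  class(out) <- c("roi_quant", "data.frame")
  out
}

#' Read an RGB micrograph
#'
#' Reads a PNG (or, when the `tiff` package is available, a TIFF) image into
#' a height x width x 3 array with channels normalized to `[0, 1]`. A
#' grayscale image is replicated across channels; an alpha channel is
#' dropped.
#'
#' @param path image file path.
#' @return Numeric array, height x width x 3, in `[0, 1]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    stop_param("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_param("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to PNG
#'
#' @param image height x width x 3 array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a binary ROI mask image
#'
#' Any pixel with intensity above 0.5 (first channel) is inside the ROI.
#'
#' @param path mask image path (PNG/TIFF).
#' @return Logical height x width matrix.
#' @export
read_roi_mask <- function(path) {
  img <- read_rgb_image(path)
  img[, , 1] > 0.5
}

#' Rasterize a polygon ROI to a mask
#'
#' Even-odd-rule point-in-polygon test on pixel centres, for ROIs supplied
#' as a vertex list rather than a mask image.
#'
#' @param width,height mask size in pixels.
#' @param xy two-column matrix of polygon vertices in pixel coordinates
#'   (x = column, y = row).
#' @return Logical height x width matrix.
#' @export
polygon_mask <- function(width, height, xy) {
  if (!is.matrix(xy) || ncol(xy) != 2 || nrow(xy) < 3)
    stop_param("xy must be a >=3-row matrix of (x, y) vertices")
  mask <- matrix(FALSE, height, width)
  xs <- xy[, 1]; ys <- xy[, 2]
  n <- nrow(xy)
  for (row in seq_len(height)) {
    py <- row - 0.5
    xcross <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      y1 <- ys[k]; y2 <- ys[k2]
      if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
        xcross <- c(xcross, xs[k] + (py - y1) / (y2 - y1) * (xs[k2] - xs[k]))
      }
    }
    if (length(xcross)) {
      xcross <- sort(xcross)
      for (i in seq(1, length(xcross) - 1, by = 2)) {
        cols <- which(seq_len(width) - 0.5 >= xcross[i] &
                      seq_len(width) - 0.5 < xcross[i + 1])
        mask[row, cols] <- TRUE
      }
    }
  }
  mask
}
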