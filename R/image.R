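#' RGB field image container
#'
#' A lightweight container for an 8-bit RGB raster, stored as an integer
#' array indexed `[row, col, channel]` with channels in R, G, B order and
#' values in `[0, 255]`. Pixel centres sit at integer (row, col) coordinates,
#' 0-based, with row 0 at the top of the image.
#'
#' @param data Integer array of dimension `height x width x 3`, values in
#'   `[0, 255]`.
#' @param gsd Optional ground-sampling distance in cm per pixel.
#'
#' @return An object of class `rice_image` with elements `data` (the array),
#'   `width`, `height` and `gsd`.
#' @export
rice_image <- function(data, gsd = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L) {
    abort("`data` must be a height x width x 3 array.", class = "ricevor_invalid_input")
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    abort("Channel values must be in [0, 255] with no missing values.",
          class = "ricevor_invalid_input")
  }
  if (!is.null(gsd)) check_gsd(gsd)
  structure(
    list(
      data = array(as.integer(round(data)), dim = dim(data)),
      height = dim(data)[1],
      width = dim(data)[2],
      gsd = gsd
    ),
    class = "rice_image"
  )
}

#' @export
print.rice_image <- function(x, ...) {
  cat(sprintf(
    "<rice_image> %d x %d px%s\n", x$height, x$width,
    if (is.null(x$gsd)) "" else sprintf(", gsd %.3g cm/px", x$gsd)
  ))
  invisible(x)
}

check_gsd <- function(gsd) {
  if (!is.numeric(gsd) || length(gsd) != 1L || is.na(gsd) || gsd <= 0) {
    abort("`gsd` must be a single positive number (cm per pixel).",
          class = "ricevor_invalid_parameter")
  }
  invisible(gsd)
}

#' Read a field image from PNG or JPEG
#'
#' Reads an 8-bit RGB raster into a [rice_image()]. Greyscale images are
#' rejected; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @inheritParams rice_image
#' @return A [rice_image()].
#' @export
read_field_image <- function(path, gsd = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path), class = "ricevor_io_error")
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      abort(sprintf("Failed to read image '%s': %s", path, conditionMessage(e)),
            class = "ricevor_io_error")
    }
  )
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) < 3L || dim(dat)[3] < 3L) {
    abort("Image must have three colour channels (8-bit RGB).",
          class = "ricevor_invalid_input")
  }
  # EBImage stores [x = col, y = row, channel] in [0, 1]
  arr <- array(0L, dim = c(dim(dat)[2], dim(dat)[1], 3L))
  for (ch in 1:3) arr[, , ch] <- as.integer(round(t(dat[, , ch]) * 255))
  rice_image(arr, gsd = gsd)
}

#' Write a field image to PNG
#'
#' @param image A [rice_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "rice_image"))
  dat <- array(0, dim = c(image$width, image$height, 3L))
  for (ch in 1:3) dat[, , ch] <- t(image$data[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path, type = "png")
  invisible(path)
}

#' Detection pipeline parameters
#'
#' Tunable constants of the cluster-recognition pipeline. Defaults are the
#' operating point for light-yellow seedlings on dark soil 5-8 days after
#' transplanting: the colour rule `(R + G)/2 > 220 & B < 200` separates
#' seedlings from soil and from high-blue water bubbles; components with
#' second-moment major axis length below 3 px are treated as noise; a
#' radius-11 disc dilation merges the shoots of one hill; components above
#' the 85th area percentile are candidate merged hills and are split by a
#' radius-5 disc erosion, keeping eroded remnants with more than 400 px and
#' major axis above 40 px.
#'
#' @param rg_threshold `(R + G)/2` must exceed this (default 220).
#' @param b_threshold `B` must be strictly below this (default 200).
#' @param min_denoise_major_axis Components with smaller major axis length
#'   are removed (default 3 px).
#' @param dilation_radius Disc radius of the merge dilation (default 11 px).
#' @param split_quantile Area quantile separating directly accepted
#'   components from erosion-refined ones (default 0.85; type-7 linear
#'   interpolation between order statistics).
#' @param erosion_radius Disc radius of the split erosion (default 5 px).
#' @param refine_min_area Eroded remnants need strictly more pixels than
#'   this (default 400).
#' @param refine_min_major_axis Eroded remnants need a strictly larger major
#'   axis than this (default 40 px).
#' @param connectivity Pixel connectivity for component labeling, 4 or 8
#'   (default 8).
#' @return A `rice_detection_params` list.
#' @export
detection_params <- function(rg_threshold = 220,
                             b_threshold = 200,
                             min_denoise_major_axis = 3,
                             dilation_radius = 11,
                             split_quantile = 0.85,
                             erosion_radius = 5,
                             refine_min_area = 400,
                             refine_min_major_axis = 40,
                             connectivity = 8) {
  p <- list(
    rg_threshold = rg_threshold, b_threshold = b_threshold,
    min_denoise_major_axis = min_denoise_major_axis,
    dilation_radius = dilation_radius, split_quantile = split_quantile,
    erosion_radius = erosion_radius, refine_min_area = refine_min_area,
    refine_min_major_axis = refine_min_major_axis,
    connectivity = connectivity
  )
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  ok <- num1(p$rg_threshold) && p$rg_threshold >= 0 && p$rg_threshold <= 255 &&
    num1(p$b_threshold) && p$b_threshold >= 0 && p$b_threshold <= 255 &&
    num1(p$min_denoise_major_axis) && p$min_denoise_major_axis >= 0 &&
    num1(p$dilation_radius) && p$dilation_radius >= 1 &&
    num1(p$split_quantile) && p$split_quantile > 0 && p$split_quantile < 1 &&
    num1(p$erosion_radius) && p$erosion_radius >= 1 &&
    num1(p$refine_min_area) && p$refine_min_area >= 0 &&
    num1(p$refine_min_major_axis) && p$refine_min_major_axis >= 0 &&
    num1(p$connectivity) && p$connectivity %in% c(4, 8)
  if (!ok) {
    abort("Invalid detection parameters: thresholds in [0,255], radii >= 1, quantile in (0,1), minimum sizes >= 0, connectivity 4 or 8.",
          class = "ricevor_invalid_parameter")
  }
  structure(p, class = "rice_detection_params")
}
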