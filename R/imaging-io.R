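#' Plate image objects
#'
#' A `plate_image` bundles an H x W x 3 raster (values in `[0, 1]`,
#' `pixels[y, x, channel]`, 0-based coordinates with x = column, y = row in
#' all reported positions) with its acquisition metadata: the inventory item
#' the dish belongs to, the capture date and the source file.
#'
#' @param pixels numeric array `H x W x 3` with values in `[0, 1]`; both
#'   dimensions must be at least 64 px.
#' @param item_id integer id of the imaged inventory item (optional).
#' @param date capture date (`Date` or coercible; optional).
#' @param source_path path of the image file this raster came from (optional).
#'
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, item_id = NA_integer_, date = as.Date(NA),
                        source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_frondkit("`pixels` must be an H x W x 3 array", "frondkit_input_error")
  }
  if (any(dim(pixels)[1:2] < 64)) {
    stop_frondkit("image must be at least 64 x 64 px", "frondkit_input_error")
  }
  structure(
    list(pixels = pixels, item_id = as.integer(item_id),
         date = as.Date(date), source_path = source_path),
    class = "plate_image"
  )
}

#' Read a plate image from a JPEG/PNG/TIFF file
#'
#' @param path image file path.
#' @inheritParams plate_image
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path, item_id = NA_integer_, date = as.Date(NA)) {
  if (!file.exists(path)) {
    stop_frondkit(paste0("image file not found: ", path), "frondkit_input_error")
  }
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  px <- aperm(px, c(2, 1, 3))  # EBImage stores x,y; we use row = y
  plate_image(px, item_id = item_id, date = date, source_path = path)
}

#' Write a plate image (or raw array) to a PNG file
#'
#' @param image a [plate_image()] or an H x W x 3 array in `[0, 1]`.
#' @param path output file path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  EBImage::writeImage(
    EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color"), path
  )
  invisible(path)
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %d x %d px, item %s, date %s\n", d[1], d[2],
              ifelse(is.na(x$item_id), "?", x$item_id),
              ifelse(is.na(x$date), "?", format(x$date))))
  invisible(x)
}

#' Green-segmentation thresholds
#'
#' Bounds in hue/saturation/value space that classify a pixel as duckweed
#' green. The defaults (hue 70-170 degrees, i.e. 35-85 in the 0-179 hue
#' convention common in computer-vision tooling; saturation >= 60/255;
#' value >= 40/255) are a reproducible stand-in for a manually tuned
#' threshold and can be overridden per call or via [run_config()].
#'
#' @param hue length-2 numeric, hue bounds in degrees (0-360).
#' @param sat_min minimum saturation in `[0, 1]`.
#' @param val_min minimum value (brightness) in `[0, 1]`.
#' @return A list of class `green_thresholds`.
#' @export
green_thresholds <- function(hue = c(70, 170), sat_min = 60 / 255,
                             val_min = 40 / 255) {
  stopifnot(length(hue) == 2, hue[1] < hue[2], sat_min >= 0, val_min >= 0)
  structure(list(hue = as.numeric(hue), sat_min = sat_min, val_min = val_min),
            class = "green_thresholds")
}
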