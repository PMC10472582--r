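#' Crop a plate image to the dish and downscale
#'
#' Crops the dish's bounding square (clamped to the frame with a warning if
#' the dish touches the border) and resizes it to `target_width` pixels.
#' The mm-per-pixel scale after resizing is
#' `diameter_mm / (2 * radius_px_after_resize)`.
#'
#' @param image a [plate_image()].
#' @param dish a `dish_detection` from [detect_dish()].
#' @param target_width width in pixels of the downscaled crop (default 700).
#'
#' @return An object of class `plate_crop`: list with `image` (the cropped
#'   [plate_image()]), `dish` (detection re-expressed in cropped
#'   coordinates) and `scale_mm_per_px`.
#' @export
crop_and_downscale <- function(image, dish, target_width = 700) {
  stopifnot(inherits(dish, "dish_detection"), target_width > 0)
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  cx <- dish$center_xy[["x"]]; cy <- dish$center_xy[["y"]]
  r <- dish$radius_px
  side <- round(2 * r)
  x0 <- round(cx - r); y0 <- round(cy - r)
  x1 <- x0 + side - 1; y1 <- y0 + side - 1
  cl_x0 <- max(x0, 0); cl_y0 <- max(y0, 0)
  cl_x1 <- min(x1, W - 1); cl_y1 <- min(y1, H - 1)
  if (cl_x0 != x0 || cl_y0 != y0 || cl_x1 != x1 || cl_y1 != y1) {
    warn("dish bounding box extends beyond the frame; crop clamped")
  }
  crop <- px[(cl_y0 + 1):(cl_y1 + 1), (cl_x0 + 1):(cl_x1 + 1), , drop = FALSE]
  fct <- target_width / ncol(crop)
  if (abs(fct - 1) > 1e-9) {
    img <- EBImage::Image(aperm(crop, c(2, 1, 3)), colormode = "Color")
    img <- EBImage::resize(img, w = target_width)
    crop <- aperm(EBImage::imageData(img), c(2, 1, 3))
    crop[crop < 0] <- 0; crop[crop > 1] <- 1
  }
  r_new <- r * fct
  dish_new <- structure(
    list(center_xy = c(x = (cx - cl_x0) * fct, y = (cy - cl_y0) * fct),
         radius_px = r_new, diameter_mm = dish$diameter_mm,
         support = dish$support),
    class = "dish_detection"
  )
  structure(
    list(
      image = plate_image(crop, item_id = image$item_id, date = image$date,
                          source_path = image$source_path),
      dish = dish_new,
      scale_mm_per_px = dish$diameter_mm / (2 * r_new)
    ),
    class = "plate_crop"
  )
}

#' Segment green frond pixels
#'
#' Classifies pixels by hue/saturation/value bounds ([green_thresholds()]),
#' forces everything outside the dish circle to `FALSE`, and removes
#' connected components smaller than `min_speck_px` pixels (sensor-noise
#' specks; set `min_speck_px = 0` to disable).
#'
#' @param x a `plate_crop` from [crop_and_downscale()], or a [plate_image()]
#'   / raw array (then supply `dish`, or `NULL` for no circular restriction,
#'   as for dissection cards).
#' @param dish optional `dish_detection` in the coordinates of `x`.
#' @param thresholds a [green_thresholds()].
#' @param min_speck_px minimum component size kept, in pixels.
#'
#' @return An object of class `green_mask`: list with the logical `mask`
#'   (row = y), the `thresholds` used and the `dish` (possibly `NULL`).
#' @export
segment_green <- function(x, dish = NULL, thresholds = green_thresholds(),
                          min_speck_px = 10) {
  if (inherits(x, "plate_crop")) {
    dish <- dish %||% x$dish
    x <- x$image
  }
  px <- if (inherits(x, "plate_image")) x$pixels else x
  hsv <- to_hsv(px)
  mask <- hsv$h >= thresholds$hue[1] & hsv$h <= thresholds$hue[2] &
    hsv$s >= thresholds$sat_min & hsv$v >= thresholds$val_min
  if (!is.null(dish)) {
    d2 <- pixel_dist2(nrow(mask), ncol(mask),
                      dish$center_xy[["x"]], dish$center_xy[["y"]])
    mask <- mask & (d2 <= dish$radius_px^2)
  }
  mask <- remove_specks(mask, min_speck_px)
  structure(list(mask = mask, thresholds = thresholds, dish = dish),
            class = "green_mask")
}

#' Convert a green-pixel mask into a calibrated area
#'
#' `area_mm2 = green_pixel_count * scale_mm_per_px^2`. When the mask carries
#' a dish, the area is additionally bounded above by the physical dish area
#' `pi * (diameter_mm / 2)^2` (rasterisation can overshoot by a fraction of
#' a square millimetre on a saturated dish).
#'
#' @param mask a `green_mask` from [segment_green()] (or a logical matrix).
#' @param scale_mm_per_px mm per pixel of the mask's frame.
#' @param item_id,date metadata copied into the output row.
#'
#' @return A one-row tibble: `item_id`, `date`, `green_pixel_count`,
#'   `scale_mm_per_px`, `area_mm2`.
#' @export
measure_area <- function(mask, scale_mm_per_px, item_id = NA_integer_,
                         date = as.Date(NA)) {
  if (!is_scalar_pos(scale_mm_per_px)) {
    stop_frondkit("`scale_mm_per_px` must be a positive scalar",
                  "frondkit_input_error")
  }
  m <- if (inherits(mask, "green_mask")) mask$mask else mask
  count <- sum(m)
  area <- count * scale_mm_per_px^2
  if (inherits(mask, "green_mask") && !is.null(mask$dish)) {
    bound <- pi * (mask$dish$diameter_mm / 2)^2
    area <- min(area, bound)
  }
  tibble(item_id = as.integer(item_id), date = as.Date(date),
         green_pixel_count = as.integer(count),
         scale_mm_per_px = scale_mm_per_px, area_mm2 = area)
}

#' Measure frond area in one plate photograph
#'
#' Runs the full chain [detect_dish()] -> [crop_and_downscale()] ->
#' [segment_green()] -> [measure_area()] on a single image.
#'
#' @param image a [plate_image()] or a file path.
#' @param diameter_mm physical dish diameter in mm.
#' @param target_width downscaled crop width in px.
#' @param thresholds a [green_thresholds()].
#' @param min_speck_px see [segment_green()].
#' @param expected_radius_frac see [detect_dish()].
#' @param item_id,date metadata (defaults taken from the image).
#'
#' @return A one-row measurement tibble (see [measure_area()]).
#' @export
measure_plate <- function(image, diameter_mm = 95, target_width = 700,
                          thresholds = green_thresholds(), min_speck_px = 10,
                          expected_radius_frac = c(0.30, 0.49),
                          item_id = NULL, date = NULL) {
  if (is.character(image)) image <- read_plate_image(image)
  dish <- detect_dish(image, expected_radius_frac = expected_radius_frac,
                      diameter_mm = diameter_mm)
  crop <- crop_and_downscale(image, dish, target_width = target_width)
  mask <- segment_green(crop, thresholds = thresholds,
                        min_speck_px = min_speck_px)
  measure_area(mask, crop$scale_mm_per_px,
               item_id = item_id %||% image$item_id,
               date = date %||% image$date)
}
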