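#' Analyze a frond-dissection photograph
#'
#' For an image of manually separated fronds on a white card: green connected
#' components are detected with the standard segmentation thresholds, small
#' or non-circular components (debris, stipe fragments) are filtered out,
#' and each remaining frond is sized by its minimum enclosing circle. With
#' `n_ramets` (the number of clonal units that were dissected; always given
#' explicitly) the fronds-per-ramet ratio is computed.
#'
#' @param image a [plate_image()], array or file path of the dissection card.
#' @param scale_mm_per_px known mm-per-pixel of the photograph.
#' @param n_ramets number of ramets dissected onto the card (required).
#' @param thresholds a [green_thresholds()].
#' @param min_area_px components smaller than this are discarded.
#' @param min_circularity components with `4*pi*area/perimeter^2` below this
#'   are discarded.
#'
#' @return An object of class `frond_set`: list with `fronds` (tibble
#'   `frond_index`, `x`, `y`, `diameter_mm`), `n_ramets` and
#'   `fronds_per_ramet`.
#' @export
analyze_fronds <- function(image, scale_mm_per_px, n_ramets,
                           thresholds = green_thresholds(),
                           min_area_px = 30, min_circularity = 0.5) {
  if (missing(n_ramets)) {
    stop_frondkit("`n_ramets` must be given explicitly", "frondkit_input_error")
  }
  if (!is_scalar_pos(scale_mm_per_px)) {
    stop_frondkit("`scale_mm_per_px` must be a positive scalar",
                  "frondkit_input_error")
  }
  if (is.character(image)) image <- read_plate_image(image)
  gm <- segment_green(image, dish = NULL, thresholds = thresholds,
                      min_speck_px = 0)
  lab <- label_components(gm$mask)
  n_comp <- max(lab)
  fronds <- tibble(frond_index = integer(), x = numeric(), y = numeric(),
                   diameter_mm = numeric())
  if (n_comp > 0) {
    shp <- EBImage::computeFeatures.shape(EBImage::Image(t(lab)))
    keep <- which(shp[, "s.area"] >= min_area_px &
                    4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2 >=
                    min_circularity)
    rows <- map(keep, function(k) {
      idx <- which(lab == k)
      yy <- ((idx - 1) %% nrow(lab))          # 0-based row
      xx <- ((idx - 1) %/% nrow(lab))         # 0-based col
      mec <- min_enclosing_circle(xx, yy)
      tibble(x = mec$cx, y = mec$cy,
             diameter_mm = (mec$d + 1) * scale_mm_per_px)  # +1 px pixel extent
    })
    fronds <- list_rbind(rows)
    if (nrow(fronds) > 0) {
      fronds <- arrange(fronds, .data$y, .data$x)
      fronds$frond_index <- seq_len(nrow(fronds))
      fronds <- select(fronds, "frond_index", "x", "y", "diameter_mm")
    }
  }
  if (n_ramets == 0 && nrow(fronds) > 0) {
    stop_frondkit("fronds detected but `n_ramets` is 0: ratio undefined",
                  "frondkit_input_error")
  }
  structure(
    list(fronds = fronds, n_ramets = as.integer(n_ramets),
         fronds_per_ramet = if (n_ramets > 0) nrow(fronds) / n_ramets else NA_real_),
    class = "frond_set"
  )
}

#' @export
print.frond_set <- function(x, ...) {
  cat(sprintf("<frond_set> %d fronds, %d ramets, %.2f fronds/ramet\n",
              nrow(x$fronds), x$n_ramets,
              ifelse(is.na(x$fronds_per_ramet), NA, x$fronds_per_ramet)))
  if (nrow(x$fronds)) print(x$fronds, n = 5)
  invisible(x)
}

# approximate minimum enclosing circle via the farthest pair of convex-hull
# points; exact for the near-circular fronds this is applied to
min_enclosing_circle <- function(x, y) {
  if (length(x) == 1) return(list(cx = x, cy = y, d = 0))
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  dm <- outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  list(cx = (hx[ij[1]] + hx[ij[2]]) / 2, cy = (hy[ij[1]] + hy[ij[2]]) / 2,
       d = sqrt(max(dm)))
}
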