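#' Plot growth curves on a log area scale
#'
#' @param curves tibble with `item_id`, `t`, `area_mm2` and optionally a
#'   treatment column (`dose_mM`, `storage_days`, `arm`) used for colour.
#' @param design selects the colour column when present.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(curves, design = "dose_response") {
  col <- intersect(c("dose_mM", "storage_days", "arm", "treatment"),
                   names(curves))[1]
  g <- ggplot(curves, aes(x = .data$t, y = .data$area_mm2,
                          group = .data$item_id))
  g <- if (!is.na(col)) {
    g + geom_line(aes(colour = factor(.data[[col]]))) +
      labs(colour = col)
  } else {
    g + geom_line()
  }
  g + scale_y_log10() +
    labs(x = "days since first image", y = expression(area ~ (mm^2)),
         title = "Frond area growth curves")
}

#' @export
autoplot.growth_curve <- function(object, ...) {
  plot_growth_curves(object)
}

#' @export
autoplot.replicate_series <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$mean_area,
                     colour = factor(.data$treatment))) +
    geom_line() +
    geom_pointrange(aes(ymin = .data$mean_area - .data$sd_area,
                        ymax = .data$mean_area + .data$sd_area), size = 0.2) +
    scale_y_log10() +
    labs(x = "days", y = expression(mean ~ area ~ (mm^2)),
         colour = "treatment",
         title = "Replicate-averaged growth")
}

#' @export
autoplot.hill_fit <- function(object, n_grid = 200, ...) {
  dmax <- max(object$data$dose)
  grid <- tibble(dose = seq(0, dmax, length.out = n_grid))
  grid$response <- predict(object, grid)
  ggplot(object$data, aes(x = .data$dose, y = .data$response)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = "dose (mM)", y = "normalized growth",
         title = "Hill dose-response fit")
}

#' @export
autoplot.decay_fit <- function(object, n_grid = 200, ...) {
  tmax <- max(object$data$storage_days)
  grid <- tibble(storage_days = seq(0, tmax, length.out = n_grid))
  grid$rgr <- predict(object, grid)
  g <- ggplot(object$data, aes(x = .data$storage_days, y = .data$rgr)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    geom_hline(yintercept = object$viability_threshold, linetype = 2) +
    labs(x = "storage duration (days)", y = "RGR (10-day area ratio)",
         title = "Storage-viability decay fit")
  if (is.finite(object$viability_limit_days)) {
    g <- g + geom_vline(xintercept = object$viability_limit_days,
                        linetype = 3)
  }
  g
}

#' @export
autoplot.tukey_grouping <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$treatment, y = .data$mean, label = .data$letters)) +
    geom_col(fill = "grey80", colour = "grey30") +
    geom_text(vjust = -0.5) +
    labs(x = "treatment", y = "group mean",
         title = sprintf("Tukey significance groups (alpha = %g)",
                         attr(object, "alpha")))
}

#' Debug overlay: detected dish circle and green mask outline
#'
#' @param crop a `plate_crop`.
#' @param mask a `green_mask` for the crop.
#' @param path optional PNG path; when given the overlay is written there.
#' @return The overlay as a [plate_image()], invisibly.
#' @export
plot_overlay <- function(crop, mask, path = NULL) {
  px <- crop$image$pixels
  m <- mask$mask
  H <- nrow(m); W <- ncol(m)
  # mask outline: mask pixels with a non-mask 4-neighbour
  nb <- m & !(m[c(1, 1:(H - 1)), ] & m[c(2:H, H), ] &
                m[, c(1, 1:(W - 1))] & m[, c(2:W, W)])
  d2 <- pixel_dist2(H, W, crop$dish$center_xy[["x"]],
                    crop$dish$center_xy[["y"]])
  ring <- abs(sqrt(d2) - crop$dish$radius_px) <= 1
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[nb] <- c(1, 0, 0)[ch]
    pl[ring] <- c(0, 0.4, 1)[ch]
    px[, , ch] <- pl
  }
  out <- plate_image(px, item_id = crop$image$item_id, date = crop$image$date)
  if (!is.null(path)) write_plate_image(out, path)
  invisible(out)
}
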