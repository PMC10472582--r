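#' Build a growth curve from per-image area measurements
#'
#' Re-bases times to the first capture date (t = 0) and averages duplicate
#' same-day measurements. Input rows must all belong to one item.
#'
#' @param measurements tibble with columns `item_id`, `area_mm2`, and either
#'   `date` (Date) or `day` (numeric days).
#'
#' @return A tibble of class `growth_curve` with columns `item_id`, `t`
#'   (days since first image) and `area_mm2`, sorted by `t`.
#' @export
build_growth_curve <- function(measurements) {
  m <- as_tibble(measurements)
  if (!"area_mm2" %in% names(m)) {
    stop_frondkit("`measurements` needs an `area_mm2` column",
                  "frondkit_input_error")
  }
  ids <- unique(m$item_id)
  if (length(ids) != 1) {
    stop_frondkit("measurements mix item_ids; build one curve per item",
                  "frondkit_input_error")
  }
  if (nrow(m) < 2) {
    stop_frondkit("need at least 2 measurements to build a growth curve",
                  "frondkit_input_error")
  }
  t_raw <- if ("day" %in% names(m)) as.numeric(m$day)
           else as.numeric(as.Date(m$date) - min(as.Date(m$date)))
  t_raw <- t_raw - min(t_raw)
  out <- tibble(item_id = ids, t = t_raw, area_mm2 = m$area_mm2) |>
    group_by(.data$item_id, .data$t) |>
    summarise(area_mm2 = mean(.data$area_mm2), .groups = "drop") |>
    arrange(.data$t)
  if (any(out$area_mm2 < 0)) {
    stop_frondkit("negative areas in growth curve", "frondkit_input_error")
  }
  class(out) <- c("growth_curve", class(out))
  out
}

#' Normalized growth: final area over initial area
#'
#' @param curve a [build_growth_curve()] result.
#' @return The ratio `area(t_last) / area(0)`.
#' @export
normalized_growth <- function(curve) {
  a0 <- curve$area_mm2[1]
  if (a0 <= 0) {
    stop_frondkit("initial area is zero; normalized growth undefined",
                  "frondkit_input_error")
  }
  curve$area_mm2[nrow(curve)] / a0
}

#' Relative growth rate over a fixed window
#'
#' The area at the time point nearest `window_days` (ties broken towards the
#' later point, accommodating irregular imaging intervals) divided by the
#' area at t = 0.
#'
#' @param curve a [build_growth_curve()] result.
#' @param window_days growth window in days (default 10).
#' @return The RGR ratio.
#' @export
compute_rgr <- function(curve, window_days = 10) {
  tmax <- max(curve$t)
  if (tmax < window_days) {
    stop_frondkit(sprintf("curve spans %.1f days, shorter than the %g-day window",
                          tmax, window_days), "frondkit_window_error")
  }
  a0 <- curve$area_mm2[1]
  if (a0 <= 0) {
    stop_frondkit("initial area is zero; RGR undefined", "frondkit_input_error")
  }
  dist <- abs(curve$t - window_days)
  cand <- which(dist == min(dist))
  i <- cand[which.max(curve$t[cand])]   # later point wins ties
  curve$area_mm2[i] / a0
}

#' Replicate-averaged growth series
#'
#' Averages growth curves across biological replicates of the same treatment
#' at each shared time point; the spread is the sample standard deviation
#' (n - 1 denominator), undefined (`NA`) where fewer than two replicates
#' share a time point.
#'
#' @param measurements tibble with `item_id`, `area_mm2`, `date` or `day`,
#'   and a `treatment` column (any label: dose, storage duration, arm).
#'
#' @return A tibble of class `replicate_series`: `treatment`, `t`, `n`,
#'   `mean_area`, `sd_area`.
#' @export
replicate_series <- function(measurements) {
  m <- as_tibble(measurements)
  stopifnot(all(c("item_id", "area_mm2", "treatment") %in% names(m)))
  curves <- m |>
    group_by(.data$treatment, .data$item_id) |>
    group_split() |>
    map(function(d) {
      cv <- build_growth_curve(d)
      cv$treatment <- d$treatment[1]
      cv
    }) |>
    list_rbind()
  out <- curves |>
    group_by(.data$treatment, .data$t) |>
    summarise(n = dplyr::n(), mean_area = mean(.data$area_mm2),
              sd_area = ifelse(dplyr::n() >= 2, sd(.data$area_mm2), NA_real_),
              .groups = "drop") |>
    arrange(.data$treatment, .data$t)
  class(out) <- c("replicate_series", class(out))
  out
}
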