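#' Run configuration
#'
#' All tunable parameters of the end-to-end workflows in one place, with a
#' lossless JSON file form ([run_config_save()] / [run_config_load()]).
#'
#' @param dish_diameter_mm physical dish diameter (default 95 mm).
#' @param thresholds a [green_thresholds()].
#' @param target_width downscaled crop width in px (default 700).
#' @param rgr_window_days RGR window (default 10 days).
#' @param viability_threshold RGR defining loss of viability (default 1.0).
#' @param alpha Tukey significance level (default 0.05).
#' @param expected_radius_frac dish-radius search band, fraction of the
#'   minimum image dimension.
#' @param min_speck_px speck-removal threshold in px.
#' @param seed RNG seed for anything stochastic downstream.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dish_diameter_mm = 95, thresholds = green_thresholds(),
                       target_width = 700, rgr_window_days = 10,
                       viability_threshold = 1.0, alpha = 0.05,
                       expected_radius_frac = c(0.30, 0.49),
                       min_speck_px = 10, seed = 1) {
  num <- c(dish_diameter_mm, target_width, rgr_window_days,
           viability_threshold, alpha)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop_frondkit("all numeric config fields must be positive",
                  "frondkit_input_error")
  }
  structure(
    list(dish_diameter_mm = dish_diameter_mm, thresholds = thresholds,
         target_width = target_width, rgr_window_days = rgr_window_days,
         viability_threshold = viability_threshold, alpha = alpha,
         expected_radius_frac = expected_radius_frac,
         min_speck_px = min_speck_px, seed = seed),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
run_config_save <- function(config, path) {
  doc <- unclass(config)
  doc$thresholds <- unclass(doc$thresholds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
run_config_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    dish_diameter_mm = doc$dish_diameter_mm,
    thresholds = green_thresholds(doc$thresholds$hue, doc$thresholds$sat_min,
                                  doc$thresholds$val_min),
    target_width = doc$target_width, rgr_window_days = doc$rgr_window_days,
    viability_threshold = doc$viability_threshold, alpha = doc$alpha,
    expected_radius_frac = doc$expected_radius_frac,
    min_speck_px = doc$min_speck_px, seed = doc$seed
  )
}

#' Run a whole experiment workflow end to end
#'
#' Takes either a simulated dataset ([simulate_experiment()]) or an image
#' directory with a manifest (`item_id`, `day` or `date`, `path`) plus a
#' treatment table, measures every image, builds per-dish growth curves and
#' RGRs, then fits the design's model: a Hill dose-response curve plus
#' Tukey letters (`dose_response`), an exponential storage-viability decay
#' (`storage`), or replicate-averaged recovery series (`recovery`). All
#' tables, fits, plots and a run log are written under `out_dir`.
#'
#' Images without a treatment row are listed in an exclusions table and the
#' run continues without them.
#'
#' @param design `"dose_response"`, `"recovery"` or `"storage"`.
#' @param dataset an `experiment_data` (alternative to images).
#' @param manifest image manifest tibble/CSV path (`item_id`, `day` or
#'   `date`, `path`).
#' @param treatments treatment tibble/CSV path (`item_id` + design column:
#'   `dose_mM`, `storage_days` or `arm`/`recovery_days`).
#' @param config a [run_config()].
#' @param out_dir output directory (`NULL`: nothing written).
#' @return A list of class `frond_report`: measurements, curves, `rgr`
#'   table, fitted model(s), grouping, exclusions, output paths.
#' @export
run_workflow <- function(design = c("dose_response", "recovery", "storage"),
                         dataset = NULL, manifest = NULL, treatments = NULL,
                         config = run_config(), out_dir = NULL) {
  design <- match.arg(design)
  config_doc <- unclass(config)
  config_doc$thresholds <- unclass(config_doc$thresholds)
  log_lines <- c(
    sprintf("frondkit %s", as.character(packageVersion("frondkit"))),
    sprintf("design: %s", design),
    sprintf("config hash: %s", hash(config_doc)),
    sprintf("config: %s", jsonlite::toJSON(config_doc, auto_unbox = TRUE))
  )
  exclusions <- tibble(item_id = integer(), reason = character(),
                       path = character())

  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "experiment_data"))
    measurements <- rename(dataset$areas, t = "day")
    treatments <- dataset$treatments
    log_lines <- c(log_lines,
                   sprintf("input: simulated dataset (%d records)",
                           nrow(measurements)))
  } else {
    if (is.character(manifest)) manifest <- readr::read_csv(manifest,
                                                            show_col_types = FALSE)
    if (is.character(treatments)) treatments <- readr::read_csv(treatments,
                                                                show_col_types = FALSE)
    if (is.null(manifest) || nrow(manifest) == 0) {
      stop_frondkit("empty input: no images to process", "frondkit_input_error")
    }
    manifest <- as_tibble(manifest)
    treatments <- as_tibble(treatments)
    unmapped <- !manifest$item_id %in% treatments$item_id
    if (any(unmapped)) {
      exclusions <- tibble(item_id = manifest$item_id[unmapped],
                           reason = "no treatment row",
                           path = manifest$path[unmapped])
      manifest <- manifest[!unmapped, ]
    }
    if (nrow(manifest) == 0) {
      stop_frondkit("empty input: every image was excluded",
                    "frondkit_input_error")
    }
    rows <- pmap(manifest, function(item_id, path, ...) {
      extra <- list(...)
      m <- measure_plate(path, diameter_mm = config$dish_diameter_mm,
                         target_width = config$target_width,
                         thresholds = config$thresholds,
                         min_speck_px = config$min_speck_px,
                         expected_radius_frac = config$expected_radius_frac,
                         item_id = item_id)
      m$t <- as.numeric(extra$day %||% extra$date)
      m
    })
    measurements <- list_rbind(rows) |>
      select("item_id", "t", area_mm2 = "area_mm2", "green_pixel_count",
             "scale_mm_per_px")
    log_lines <- c(log_lines,
                   paste0("processed: ", manifest$path),
                   sprintf("excluded: %d image(s)", nrow(exclusions)))
  }

  meas <- measurements |> select("item_id", day = "t", "area_mm2")
  curves <- meas |>
    group_by(.data$item_id) |>
    group_split() |>
    map(build_growth_curve) |>
    list_rbind()

  window <- min(config$rgr_window_days, max(curves$t))
  rgr_tbl <- curves |>
    group_by(.data$item_id) |>
    group_split() |>
    map(function(cv) tibble(item_id = cv$item_id[1],
                            rgr = compute_rgr(cv, window_days = window))) |>
    list_rbind() |>
    left_join(treatments, by = "item_id")

  fit <- NULL; grouping <- NULL; series <- NULL
  if (design == "dose_response") {
    fit <- fit_hill(rgr_tbl, doses = "dose_mM", responses = "rgr")
    # Tukey letters need >= 2 replicates in every dose group
    if (min(table(rgr_tbl$dose_mM)) >= 2) {
      grouping <- rgr_tbl |>
        mutate(treatment = paste0(.data$dose_mM, " mM")) |>
        anova_tukey(value = "rgr", alpha = config$alpha)
    }
  } else if (design == "storage") {
    fit <- fit_storage_decay(rgr_tbl, storage_days = "storage_days",
                             rgr = "rgr",
                             viability_threshold = config$viability_threshold)
  } else {
    series <- meas |>
      left_join(treatments, by = "item_id") |>
      mutate(treatment = paste0(.data$arm, "+", .data$recovery_days, "d"),
             date = .data$day) |>
      replicate_series()
  }

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(obj, p)
      p
    }
    paths <- c(measurements = wr(measurements, "measurements.csv"),
               curves = wr(curves, "curves.csv"),
               rgr = wr(rgr_tbl, "rgr.csv"),
               exclusions = wr(exclusions, "exclusions.csv"))
    fits_doc <- list(design = design)
    if (!is.null(fit)) {
      fits_doc$fit <- list(estimates = fit$estimates, rss = fit$rss)
      if (inherits(fit, "decay_fit")) {
        fits_doc$fit$viability_limit_days <- fit$viability_limit_days
        fits_doc$fit$viability_threshold <- fit$viability_threshold
      }
    }
    p <- file.path(out_dir, "fits.json")
    jsonlite::write_json(fits_doc, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, fits = p)
    if (!is.null(grouping)) {
      paths <- c(paths, grouping = wr(as_tibble(grouping), "grouping.csv"))
    }
    # plots
    pl <- file.path(out_dir, "growth_curves.png")
    g <- plot_growth_curves(left_join(curves, treatments, by = "item_id"),
                            design = design)
    ggsave(pl, g, width = 7, height = 5, dpi = 120)
    paths <- c(paths, growth_curves_plot = pl)
    if (!is.null(fit)) {
      pf <- file.path(out_dir, paste0(design, "_fit.png"))
      ggsave(pf, autoplot(fit), width = 6, height = 4.5, dpi = 120)
      paths <- c(paths, fit_plot = pf)
    }
    log_lines <- c(log_lines, paste0("wrote: ", paths))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    paths <- c(paths, log = file.path(out_dir, "run_log.txt"))
  }

  structure(
    list(design = design, measurements = measurements, curves = curves,
         rgr = rgr_tbl, fit = fit, grouping = grouping, series = series,
         exclusions = exclusions, config = config, paths = paths),
    class = "frond_report"
  )
}

#' @export
print.frond_report <- function(x, ...) {
  cat(sprintf("<frond_report> %s: %d measurements, %d dishes, %d excluded\n",
              x$design, nrow(x$measurements),
              dplyr::n_distinct(x$measurements$item_id), nrow(x$exclusions)))
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$grouping)) print(x$grouping)
  invisible(x)
}
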