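#' Specify a synthetic duckweed experiment
#'
#' Encodes the three experiment designs with known ground truth:
#' * `dose_response`: triplicate dishes per NaCl dose (default grid
#'   0/50/100/150/300 mM) imaged every 2 days for 10 days; area follows
#'   `A(t) = A0 * exp(r(c) * t)` with the growth rate inhibited by dose
#'   through a Hill term `r(c) = r_max / (1 + (c/ec50)^hill_n)`.
#' * `storage`: dishes revived after cold storage (default grid
#'   0/6/28/232/310 days); the 10-day RGR of each replicate is drawn from
#'   `r0 * exp(-k * t_storage)` with multiplicative lognormal noise.
#' * `recovery`: mock vs salt-treated arms; the treated arm's growth rate
#'   is 0 (no recovery), the mock arm grows at `r_max`.
#'
#' Defaults mirror a typical assay regime: `A0 = 100` mm^2, `r_max = 0.2`/day,
#' `ec50 = 100` mM, `hill_n = 2`, `r0 = 6`, `k = 0.064`/day, triplicates,
#' 10-day imaging window.
#'
#' @param design `"dose_response"`, `"recovery"` or `"storage"`.
#' @param doses NaCl doses in mM (dose_response).
#' @param storage_days storage durations in days (storage).
#' @param recovery_days recovery delays in days (recovery).
#' @param replicates biological replicates per condition (>= 1).
#' @param imaging_days imaging schedule, strictly increasing from 0.
#' @param A0 initial frond area, mm^2.
#' @param r_max uninhibited growth rate, 1/day.
#' @param ec50,hill_n Hill inhibition parameters (mM, dimensionless).
#' @param r0,k storage-decay parameters (ratio, 1/day).
#' @param noise_sd multiplicative lognormal noise sd (`NULL`: 0.05 for
#'   dose_response/recovery, 0.10 for storage).
#' @param response_model for `dose_response`: `"hill_rgr"` (default) puts
#'   the Hill curve on the day-10 normalized-growth scale (top =
#'   `exp(r_max * window)`, bottom = 1), so refitting it recovers the
#'   generating `ec50`/`hill_n` exactly; `"hill_rate"` inhibits the growth
#'   rate itself, `r(c) = r_max / (1 + (c/ec50)^n)`.
#' @param seed RNG seed.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(design = c("dose_response", "recovery", "storage"),
                            doses = c(0, 50, 100, 150, 300),
                            storage_days = c(0, 6, 28, 232, 310),
                            recovery_days = c(0, 2, 4, 10),
                            replicates = 3, imaging_days = seq(0, 10, by = 2),
                            A0 = 100, r_max = 0.2, ec50 = 100, hill_n = 2,
                            r0 = 6, k = 0.064, noise_sd = NULL,
                            response_model = c("hill_rgr", "hill_rate"),
                            seed = 1) {
  design <- match.arg(design)
  response_model <- match.arg(response_model)
  if (!is_count(replicates) || replicates < 1) {
    stop_frondkit("`replicates` must be >= 1", "frondkit_spec_error")
  }
  if (imaging_days[1] != 0 || any(diff(imaging_days) <= 0)) {
    stop_frondkit("`imaging_days` must strictly increase from 0",
                  "frondkit_spec_error")
  }
  noise_sd <- noise_sd %||% if (design == "storage") 0.10 else 0.05
  structure(
    list(design = design, doses = doses, storage_days = storage_days,
         recovery_days = recovery_days, replicates = replicates,
         imaging_days = imaging_days, A0 = A0, r_max = r_max, ec50 = ec50,
         hill_n = hill_n, r0 = r0, k = k, noise_sd = noise_sd,
         response_model = response_model, seed = seed),
    class = "experiment_spec"
  )
}

#' Simulate an experiment-level dataset
#'
#' Produces per-dish area series with the matching treatment table and a
#' ground-truth record; a pure function of spec + seed. With `noise_sd = 0`
#' the series satisfy the generating equations exactly.
#'
#' @param spec an [experiment_spec()].
#' @return A list of class `experiment_data`: `areas` (tibble `item_id`,
#'   treatment columns, `replicate`, `day`, `area_mm2`), `treatments` (one
#'   row per dish), `truth` (generating parameters, incl. per-dish true
#'   rates/RGRs), `spec`.
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  with_seed(spec$seed, {
    switch(spec$design,
           dose_response = sim_dose_response(spec),
           storage = sim_storage(spec),
           recovery = sim_recovery(spec))
  })
}

sim_dose_response <- function(spec) {
  grid <- tidyr::expand_grid(dose_mM = spec$doses,
                             replicate = seq_len(spec$replicates))
  grid$item_id <- seq_len(nrow(grid))
  window <- max(spec$imaging_days)
  if (spec$response_model == "hill_rgr") {
    # Hill inhibition on the normalized-growth scale: the end-of-window
    # area ratio follows the Hill curve exactly (top = uninhibited growth,
    # bottom = 1, i.e. no net growth at saturating dose); each dish still
    # grows exponentially at the matching rate ln(RGR)/window
    top <- exp(spec$r_max * window)
    grid$rgr_true <- 1 + (top - 1) / (1 + (grid$dose_mM / spec$ec50)^spec$hill_n)
    grid$rate <- log(grid$rgr_true) / window
    hill_truth <- list(top = top, bottom = 1, ec50 = spec$ec50,
                       hill_n = spec$hill_n)
  } else {
    # literal rate inhibition: r(c) = r_max / (1 + (c/ec50)^n)
    grid$rate <- spec$r_max / (1 + (grid$dose_mM / spec$ec50)^spec$hill_n)
    grid$rgr_true <- exp(grid$rate * window)
    hill_truth <- NULL
  }
  areas <- grid |>
    tidyr::expand_grid(day = spec$imaging_days) |>
    mutate(area_mm2 = spec$A0 * exp(.data$rate * .data$day) *
             exp(rnorm(dplyr::n(), 0, spec$noise_sd))) |>
    select("item_id", "dose_mM", "replicate", "day", "area_mm2")
  new_experiment_data(spec, areas,
                      treatments = select(grid, "item_id", "dose_mM", "replicate"),
                      truth = list(A0 = spec$A0, r_max = spec$r_max,
                                   ec50 = spec$ec50, hill_n = spec$hill_n,
                                   hill_response = hill_truth,
                                   rates = select(grid, "item_id", "dose_mM",
                                                  "rate", "rgr_true")))
}

sim_storage <- function(spec) {
  grid <- tidyr::expand_grid(storage_days = spec$storage_days,
                             replicate = seq_len(spec$replicates))
  grid$item_id <- seq_len(nrow(grid))
  window <- max(spec$imaging_days)
  grid$rgr_true <- spec$r0 * exp(-spec$k * grid$storage_days)
  grid$rgr_obs <- grid$rgr_true * exp(rnorm(nrow(grid), 0, spec$noise_sd))
  grid$rate <- log(grid$rgr_obs) / window
  areas <- grid |>
    tidyr::expand_grid(day = spec$imaging_days) |>
    mutate(area_mm2 = spec$A0 * exp(.data$rate * .data$day)) |>
    select("item_id", "storage_days", "replicate", "day", "area_mm2")
  new_experiment_data(spec, areas,
                      treatments = select(grid, "item_id", "storage_days", "replicate"),
                      truth = list(A0 = spec$A0, r0 = spec$r0, k = spec$k,
                                   viability_limit_days =
                                     if (spec$r0 > 1) log(spec$r0) / spec$k else 0,
                                   rgr = select(grid, "item_id", "storage_days",
                                                "rgr_true", "rgr_obs")))
}

sim_recovery <- function(spec) {
  grid <- tidyr::expand_grid(arm = c("mock", "salt"),
                             recovery_days = spec$recovery_days,
                             replicate = seq_len(spec$replicates))
  grid$item_id <- seq_len(nrow(grid))
  grid$rate <- ifelse(grid$arm == "salt", 0, spec$r_max)
  areas <- grid |>
    tidyr::expand_grid(day = spec$imaging_days) |>
    mutate(area_mm2 = spec$A0 * exp(.data$rate * .data$day) *
             exp(rnorm(dplyr::n(), 0, spec$noise_sd))) |>
    select("item_id", "arm", "recovery_days", "replicate", "day", "area_mm2")
  new_experiment_data(spec, areas,
                      treatments = select(grid, "item_id", "arm",
                                          "recovery_days", "replicate"),
                      truth = list(A0 = spec$A0, r_max = spec$r_max,
                                   rates = select(grid, "item_id", "arm", "rate")))
}

new_experiment_data <- function(spec, areas, treatments, truth) {
  structure(list(areas = areas, treatments = treatments, truth = truth,
                 spec = spec),
            class = "experiment_data")
}

#' @export
print.experiment_data <- function(x, ...) {
  cat(sprintf("<experiment_data> design %s: %d dishes, %d area records\n",
              x$spec$design, nrow(x$treatments), nrow(x$areas)))
  invisible(x)
}

#' Render a simulated experiment to image files
#'
#' Writes one synthetic plate PNG per dish and imaging day whose rendered
#' frond area approximates the simulated area, together with a manifest
#' (`item_id`, `day`, `path`), the treatment table, a truth CSV (rendered
#' true areas) and the spec as JSON; the layout is directly consumable by
#' [run_workflow()] and the command-line interface.
#'
#' @param data an [simulate_experiment()] result.
#' @param dir output directory (created).
#' @param image_size plate image side in px.
#' @return The manifest tibble, invisibly (with a `dir` attribute).
#' @export
render_experiment_images <- function(data, dir, image_size = 480) {
  stopifnot(inherits(data, "experiment_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  radius <- 0.44 * image_size
  rows <- pmap(list(data$areas$item_id, data$areas$day, data$areas$area_mm2,
                    seq_len(nrow(data$areas))),
               function(item, day, area, i) {
    sc <- scene_for_area(area, size = image_size, radius_px = radius,
                         seed = data$spec$seed * 10000 + i)
    path <- file.path(dir, sprintf("item%03d_day%02d.png", item, day))
    write_plate_image(render_plate(sc)$image, path)
    tibble(item_id = item, day = day, path = path)
  })
  manifest <- list_rbind(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(data$treatments, file.path(dir, "treatments.csv"))
  readr::write_csv(data$areas, file.path(dir, "areas_truth.csv"))
  jsonlite::write_json(unclass(data$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}

# a scene whose rendered frond area approximates `area_mm2`, split over a
# few discs placed inside the dish
scene_for_area <- function(area_mm2, size, radius_px, diameter_mm = 95,
                           n_blobs = 4, seed = 1) {
  scale <- diameter_mm / (2 * radius_px)
  area_px <- area_mm2 / scale^2
  max_px <- pi * (radius_px * 0.8)^2
  area_px <- min(area_px, 0.5 * max_px)   # keep blobs placeable
  r_disc <- sqrt(area_px / (n_blobs * pi))
  ctr <- c((size - 1) / 2, (size - 1) / 2)
  blobs <- with_seed(seed, {
    placed <- list()
    tries <- 0
    while (length(placed) < n_blobs && tries < 400) {
      tries <- tries + 1
      rad <- sqrt(runif(1)) * (radius_px - 6 - r_disc)
      th <- runif(1, 0, 2 * pi)
      x <- ctr[1] + rad * cos(th); y <- ctr[2] + rad * sin(th)
      ok <- all(map_lgl(placed, function(p) {
        sqrt((p$cx - x)^2 + (p$cy - y)^2) > 2 * r_disc + 3
      }))
      if (ok) {
        placed[[length(placed) + 1]] <- tibble(
          cx = x, cy = y, a = r_disc, b = r_disc, angle = 0,
          hue = runif(1, 90, 150), sat = runif(1, 0.45, 0.75),
          val = runif(1, 0.40, 0.70))
      }
    }
    list_rbind(placed)
  })
  scene_spec(size = size, radius_px = radius_px, diameter_mm = diameter_mm,
             blobs = blobs, seed = seed)
}
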