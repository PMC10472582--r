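test_that("the dish is located to within 3 px / 2% radius in a rendered scene", {
  scn <- render_plate(make_scene(seed = 11, size = 800, radius_frac = 0.4375))
  dish <- detect_dish(scn$image)
  expect_lt(abs(dish$center_xy[["x"]] - 399.5), 3)
  expect_lt(abs(dish$center_xy[["y"]] - 399.5), 3)
  expect_lt(abs(dish$radius_px - 350) / 350, 0.02)
})

test_that("a uniform image has no dish; a small spurious ring does not win", {
  expect_error(detect_dish(plate_image(array(0.8, dim = c(256, 256, 3)))),
               class = "frondkit_no_dish")
  set.seed(5)
  noisy <- pmin(pmax(0.8 + rnorm(256 * 256 * 3, 0, 3 / 255), 0), 1)
  expect_error(detect_dish(plate_image(array(noisy, dim = c(256, 256, 3)))),
               class = "frondkit_no_dish")

  scn <- render_plate(make_scene(seed = 2, size = 800, n_blobs = 4))
  px <- scn$image$pixels
  ring <- abs(sqrt(frondkit:::pixel_dist2(800, 800, 200, 200)) - 60) <= 2
  for (ch in 1:3) { pl <- px[, , ch]; pl[ring] <- 0.2; px[, , ch] <- pl }
  dish <- detect_dish(plate_image(px))
  expect_lt(abs(dish$radius_px - 350) / 350, 0.02)
  expect_lt(abs(dish$center_xy[["x"]] - 399.5), 3)
})

test_that("crop scale follows the physical-diameter calibration", {
  scn <- render_plate(make_scene(seed = 11))
  dish <- detect_dish(scn$image)
  # with target 700 px and a 350 px dish the scale is 95/700 mm/px
  crop <- crop_and_downscale(scn$image, dish, target_width = 700)
  expect_equal(crop$scale_mm_per_px, 95 / 700, tolerance = 0.02)
  # native crop width: scale = 95 / (2 * 350)
  native <- crop_and_downscale(scn$image, dish, target_width = round(2 * dish$radius_px))
  expect_equal(native$scale_mm_per_px, 95 / (2 * 350), tolerance = 0.02)
  # area is insensitive to the downscale factor
  a400 <- measure_area(segment_green(crop_and_downscale(scn$image, dish, 400)),
                       crop_and_downscale(scn$image, dish, 400)$scale_mm_per_px)
  a800 <- measure_area(segment_green(crop_and_downscale(scn$image, dish, 800)),
                       crop_and_downscale(scn$image, dish, 800)$scale_mm_per_px)
  expect_lt(abs(a400$area_mm2 - a800$area_mm2) / a800$area_mm2, 0.02)
})

test_that("segmentation saturates on all-green dishes and stays silent on clear media", {
  size <- 400; r <- 170
  ctr <- (size - 1) / 2
  dish <- manual_dish(ctr, ctr, r)
  # interior entirely frond-green
  green <- array(0, dim = c(size, size, 3))
  col <- frondkit:::hsv_to_rgb(120, 0.6, 0.55)
  inside <- frondkit:::pixel_dist2(size, size, ctr, ctr) <= r^2
  for (ch in 1:3) { pl <- green[, , ch]; pl[] <- 0.8; pl[inside] <- col[ch]; green[, , ch] <- pl }
  m <- segment_green(plate_image(green), dish = dish)
  expect_gte(sum(m$mask) / sum(inside), 0.99)

  # clear medium only
  scn <- render_plate(make_scene(seed = 4, size = 400, n_blobs = 0))
  m0 <- segment_green(scn$image, dish = dish)
  expect_lt(sum(m0$mask) / sum(inside), 0.005)
})

test_that("segmentation recovers the generator's frond mask (IoU >= 0.90)", {
  for (seed in c(21, 22, 23)) {
    scn <- render_plate(make_scene(seed = seed, size = 500, n_blobs = 8))
    dish <- manual_dish((500 - 1) / 2, (500 - 1) / 2, scn$spec$radius_px)
    m <- segment_green(scn$image, dish = dish)
    iou <- sum(m$mask & scn$mask) / sum(m$mask | scn$mask)
    expect_gte(iou, 0.90)
  }
})

test_that("measured area matches ground truth within 2% and the dish bound holds", {
  scn <- render_plate(make_scene(seed = 31, size = 800))
  m <- measure_plate(scn$image)
  expect_lt(abs(m$area_mm2 - scn$true_area_mm2) / scn$true_area_mm2, 0.02)
  expect_lte(m$area_mm2, pi * 47.5^2)

  # saturated mask reproduces the closed-form dish area
  size <- 800; ctr <- (size - 1) / 2
  full <- frondkit:::pixel_dist2(size, size, ctr, ctr) <= 350^2
  gm <- structure(list(mask = full, thresholds = green_thresholds(),
                       dish = manual_dish(ctr, ctr, 350)),
                  class = "green_mask")
  a <- measure_area(gm, 95 / 700)
  expect_lt(abs(a$area_mm2 - pi * 47.5^2), 1)

  # empty mask
  expect_equal(measure_area(matrix(FALSE, 64, 64), 0.1)$area_mm2, 0)
  expect_error(measure_area(matrix(FALSE, 64, 64), -1), class = "frondkit_input_error")
})

test_that("area is monotone in the mask and equals the per-pixel oracle", {
  scn <- render_plate(make_scene(seed = 41, size = 400))
  dish <- manual_dish((400 - 1) / 2, (400 - 1) / 2, scn$spec$radius_px)
  gm <- segment_green(scn$image, dish = dish)
  scale <- 95 / (2 * scn$spec$radius_px)
  a1 <- measure_area(gm, scale)

  # oracle: explicit per-pixel loop
  count <- 0L
  for (j in seq_len(ncol(gm$mask))) count <- count + sum(gm$mask[, j])
  expect_identical(a1$green_pixel_count, count)
  expect_identical(a1$area_mm2, count * scale^2)

  # adding pixels never decreases area
  gm2 <- gm
  off <- which(!gm2$mask)[1:500]
  gm2$mask[off] <- TRUE
  expect_gte(measure_area(gm2$mask, scale)$area_mm2, a1$area_mm2)
})

test_that("measured area is invariant to 90-degree rotation and 2x rescaling", {
  scn <- render_plate(make_scene(seed = 51, size = 500, n_blobs = 5))
  m <- measure_plate(scn$image, target_width = 500)
  m_rot <- measure_plate(plate_image(rot90_px(scn$image$pixels)), target_width = 500)
  expect_lt(abs(m_rot$area_mm2 - m$area_mm2) / m$area_mm2, 0.01)

  # same scene rendered at 2x resolution, measured at its native crop width
  sp <- scn$spec
  blobs2 <- sp$blobs
  blobs2[c("cx", "cy", "a", "b")] <- blobs2[c("cx", "cy", "a", "b")] * 2
  blobs2$cx <- blobs2$cx + 0.5; blobs2$cy <- blobs2$cy + 0.5
  sp2 <- scene_spec(size = 1000, radius_px = sp$radius_px * 2, blobs = blobs2,
                    noise_sd = sp$noise_sd, seed = sp$seed)
  scn2 <- render_plate(sp2)
  m_nat <- measure_plate(scn$image, target_width = round(2 * sp$radius_px))
  m2 <- measure_plate(scn2$image, target_width = round(4 * sp$radius_px))
  expect_lt(abs(m2$area_mm2 - m_nat$area_mm2) / m_nat$area_mm2, 0.02)
})

test_that("dissection analysis counts separated fronds and sizes them in mm", {
  ds <- render_dissection(12, diameter_px = 40, spacing_px = 10, seed = 5)
  fs <- analyze_fronds(ds$image, scale_mm_per_px = 0.1, n_ramets = 5)
  expect_equal(nrow(fs$fronds), 12)
  expect_lt(abs(mean(fs$fronds$diameter_mm) - 4.0) / 4.0, 0.05)
  expect_equal(fs$fronds_per_ramet, 12 / 5)

  # blank card
  blank <- render_dissection(0, seed = 1, size = 200)
  f0 <- analyze_fronds(blank$image, 0.1, n_ramets = 3)
  expect_equal(nrow(f0$fronds), 0)

  # fronds present but no ramet count -> undefined ratio
  expect_error(analyze_fronds(ds$image, 0.1, n_ramets = 0),
               class = "frondkit_input_error")

  # ratio arithmetic: 10 fronds over 5 ramets
  ds10 <- render_dissection(10, diameter_px = 30, spacing_px = 8, seed = 9)
  expect_equal(analyze_fronds(ds10$image, 0.1, n_ramets = 5)$fronds_per_ramet, 2.0)
})

test_that("frond count matches the generator whenever discs are separated >= 3 px", {
  for (case in list(list(n = 7, d = 24, sp = 3, seed = 61),
                    list(n = 15, d = 36, sp = 6, seed = 62),
                    list(n = 4, d = 50, sp = 20, seed = 63))) {
    ds <- render_dissection(case$n, diameter_px = case$d, spacing_px = case$sp,
                            seed = case$seed)
    fs <- analyze_fronds(ds$image, 0.1, n_ramets = 3)
    expect_equal(nrow(fs$fronds), case$n)
  }
  expect_error(render_dissection(5, spacing_px = 2), class = "frondkit_placement_error")
})
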