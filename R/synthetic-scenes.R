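#' Specify a synthetic plate scene
#'
#' Describes a top-down photograph of one circular dish on a uniform
#' background: image size, dish geometry and physical diameter, colours,
#' the green frond blobs (ellipses), sensor-noise level and RNG seed.
#' Rendering ([render_plate()]) is a pure function of the spec, so the same
#' spec always yields the same image.
#'
#' @param size image side length in px (square image).
#' @param center dish centre `c(x, y)` in 0-based px (default image centre).
#' @param radius_px dish radius in px (default 0.44 * size, a dish filling
#'   most of the frame).
#' @param diameter_mm physical dish diameter (default 95 mm).
#' @param blobs tibble of frond ellipses: `cx`, `cy`, `a`, `b` (semi-axes,
#'   px), `angle` (radians), `hue`, `sat`, `val`; see [random_blobs()].
#' @param background,rim_color,media_color length-3 RGB in `[0, 1]`.
#' @param rim_half_px half-width of the dark dish rim annulus.
#' @param noise_sd Gaussian sensor noise sd (default 3/255).
#' @param vignette strength of radial darkening towards corners.
#' @param seed RNG seed for the noise.
#'
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(size = 800, center = NULL, radius_px = NULL,
                       diameter_mm = 95, blobs = NULL,
                       background = c(0.82, 0.80, 0.78),
                       rim_color = c(0.22, 0.22, 0.25),
                       media_color = c(0.87, 0.88, 0.86),
                       rim_half_px = 3, noise_sd = 3 / 255,
                       vignette = 0.06, seed = 1) {
  center <- center %||% c((size - 1) / 2, (size - 1) / 2)
  radius_px <- radius_px %||% (0.44 * size)
  blobs <- blobs %||% tibble(cx = numeric(), cy = numeric(), a = numeric(),
                             b = numeric(), angle = numeric(),
                             hue = numeric(), sat = numeric(), val = numeric())
  spec <- structure(
    list(size = size, center = center, radius_px = radius_px,
         diameter_mm = diameter_mm, blobs = as_tibble(blobs),
         background = background, rim_color = rim_color,
         media_color = media_color, rim_half_px = rim_half_px,
         noise_sd = noise_sd, vignette = vignette, seed = seed),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(spec$size >= 64, spec$radius_px > 0, spec$diameter_mm > 0)
  if (nrow(spec$blobs)) {
    d <- sqrt((spec$blobs$cx - spec$center[1])^2 +
                (spec$blobs$cy - spec$center[2])^2)
    lim <- spec$radius_px - spec$rim_half_px - 1
    if (any(d + pmax(spec$blobs$a, spec$blobs$b) > lim)) {
      stop_frondkit("blob extends outside the dish interior",
                    "frondkit_spec_error")
    }
  }
  invisible(spec)
}

#' Random frond blobs inside a dish
#'
#' Samples non-degenerate ellipses inside the dish interior with colours
#' drawn from the interior of the default segmentation gamut (20% margin,
#' so default thresholds succeed), or near its boundary when
#' `palette = "adversarial"` (for robustness checks).
#'
#' @param n number of blobs.
#' @param radius_px,center dish geometry (as in [scene_spec()]).
#' @param size_px range of blob semi-major axes in px.
#' @param aspect range of semi-minor/semi-major ratios.
#' @param palette `"interior"` or `"adversarial"`.
#' @param seed RNG seed.
#' @return A blob tibble for [scene_spec()].
#' @export
random_blobs <- function(n, radius_px, center, size_px = c(8, 30),
                         aspect = c(0.7, 1), palette = c("interior", "adversarial"),
                         seed = 1) {
  palette <- match.arg(palette)
  with_seed(seed, {
    a <- runif(n, size_px[1], size_px[2])
    b <- a * runif(n, aspect[1], aspect[2])
    # place by rejection within the admissible disc
    rmax <- radius_px - 5 - a   # leave rim margin
    rad <- sqrt(runif(n)) * pmax(rmax, 0)
    th <- runif(n, 0, 2 * pi)
    hue <- if (palette == "interior") runif(n, 90, 150) else
      sample(c(runif(ceiling(n / 2), 71, 76), runif(floor(n / 2), 164, 169)), n)
    tibble(
      cx = center[1] + rad * cos(th), cy = center[2] + rad * sin(th),
      a = a, b = b, angle = runif(n, 0, pi),
      hue = hue,
      sat = if (palette == "interior") runif(n, 0.45, 0.75) else runif(n, 0.25, 0.3),
      val = if (palette == "interior") runif(n, 0.40, 0.70) else runif(n, 0.2, 0.3)
    )
  })
}

#' Render a synthetic plate image with ground truth
#'
#' Draws the dish (light media disc with a dark rim annulus over a uniform
#' background, mild vignetting), stamps the green frond ellipses, then adds
#' Gaussian sensor noise. The returned truth mask marks exactly the
#' rendered frond pixels, and the true area converts its pixel count with
#' the spec's physical calibration.
#'
#' @param spec a [scene_spec()].
#' @param item_id,date metadata for the returned [plate_image()].
#' @return A list of class `plate_scene`: `image` ([plate_image()]), `mask`
#'   (logical truth), `true_area_mm2`, `spec`.
#' @export
render_plate <- function(spec, item_id = NA_integer_, date = as.Date(NA)) {
  validate_scene_spec(spec)
  n <- spec$size
  cx <- spec$center[1]; cy <- spec$center[2]
  d2 <- pixel_dist2(n, n, cx, cy)
  d <- sqrt(d2)
  px <- array(rep(spec$background, each = n * n), dim = c(n, n, 3))
  interior <- d < (spec$radius_px - spec$rim_half_px)
  rim <- abs(d - spec$radius_px) <= spec$rim_half_px
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[interior] <- spec$media_color[ch]
    pl[rim] <- spec$rim_color[ch]
    px[, , ch] <- pl
  }
  mask <- matrix(FALSE, n, n)
  if (nrow(spec$blobs)) {
    xs <- matrix(rep(0:(n - 1), each = n), n, n)   # x = col
    ys <- matrix(rep(0:(n - 1), n), n, n)          # y = row
    for (i in seq_len(nrow(spec$blobs))) {
      bl <- spec$blobs[i, ]
      dx <- xs - bl$cx; dy <- ys - bl$cy
      u <- dx * cos(bl$angle) + dy * sin(bl$angle)
      v <- -dx * sin(bl$angle) + dy * cos(bl$angle)
      inside <- (u / bl$a)^2 + (v / bl$b)^2 <= 1
      col <- hsv_to_rgb(bl$hue, bl$sat, bl$val)
      for (ch in 1:3) {
        pl <- px[, , ch]; pl[inside] <- col[ch]; px[, , ch] <- pl
      }
      mask <- mask | inside
    }
  }
  if (spec$vignette > 0) {
    corner <- sqrt(2) * (n - 1) / 2
    vig <- 1 - spec$vignette * (d / corner)^2
    for (ch in 1:3) px[, , ch] <- px[, , ch] * vig
  }
  if (spec$noise_sd > 0) {
    px <- with_seed(spec$seed, px + rnorm(length(px), 0, spec$noise_sd))
    px[px < 0] <- 0; px[px > 1] <- 1
  }
  scale <- spec$diameter_mm / (2 * spec$radius_px)
  structure(
    list(image = plate_image(px, item_id = item_id, date = date),
         mask = mask, true_area_mm2 = sum(mask) * scale^2, spec = spec),
    class = "plate_scene"
  )
}

#' Render a synthetic frond-dissection card with ground truth
#'
#' Places `n_fronds` non-touching green discs on a white card. Fails with a
#' placement error if the requested spacing is below 3 px or the discs do
#' not fit on the card.
#'
#' @param n_fronds number of discs.
#' @param diameter_px disc diameter(s) in px (scalar or length `n_fronds`).
#' @param spacing_px minimum gap between discs and to the card edge (>= 3).
#' @param size card side length in px (`NULL`: sized to fit).
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed (jitter, colours, noise).
#' @return A list of class `dissection_scene`: `image`, `truth` (tibble
#'   `x`, `y`, `diameter_px`), `mask`.
#' @export
render_dissection <- function(n_fronds, diameter_px = 40, spacing_px = 10,
                              size = NULL, noise_sd = 2 / 255, seed = 1) {
  if (spacing_px < 3) {
    stop_frondkit("spacing below 3 px would let fronds touch; placement refused",
                  "frondkit_placement_error")
  }
  dia <- rep_len(diameter_px, max(n_fronds, 1))
  cell <- max(dia) + spacing_px
  ncol_grid <- max(1, ceiling(sqrt(max(n_fronds, 1))))
  nrow_grid <- max(1, ceiling(max(n_fronds, 1) / ncol_grid))
  need <- max(nrow_grid, ncol_grid) * cell + spacing_px
  size <- size %||% max(need, 64)
  if (size < need) {
    stop_frondkit(sprintf("cannot place %d discs of <= %d px on a %d px card",
                          n_fronds, max(dia), size),
                  "frondkit_placement_error")
  }
  px <- with_seed(seed, {
    arr <- array(0.95, dim = c(size, size, 3))
    if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
    arr
  })
  truth <- tibble(x = numeric(), y = numeric(), diameter_px = numeric())
  mask <- matrix(FALSE, size, size)
  if (n_fronds > 0) {
    off <- (size - nrow_grid * cell) / 2
    truth <- with_seed(seed + 1, {
      map(seq_len(n_fronds), function(i) {
        r <- (i - 1) %/% ncol_grid; c <- (i - 1) %% ncol_grid
        slack <- (cell - dia[i] - spacing_px) / 2
        tibble(
          x = off + c * cell + cell / 2 + runif(1, -slack, slack),
          y = off + r * cell + cell / 2 + runif(1, -slack, slack),
          diameter_px = dia[i],
          hue = runif(1, 90, 150), sat = runif(1, 0.45, 0.75),
          val = runif(1, 0.40, 0.70)
        )
      }) |> list_rbind()
    })
    for (i in seq_len(n_fronds)) {
      d2 <- pixel_dist2(size, size, truth$x[i], truth$y[i])
      inside <- d2 <= (truth$diameter_px[i] / 2)^2
      col <- hsv_to_rgb(truth$hue[i], truth$sat[i], truth$val[i])
      for (ch in 1:3) { pl <- px[, , ch]; pl[inside] <- col[ch]; px[, , ch] <- pl }
      mask <- mask | inside
    }
    truth <- select(truth, "x", "y", "diameter_px")
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  structure(list(image = plate_image(px), truth = truth, mask = mask),
            class = "dissection_scene")
}
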