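#' Locate the petri dish in a plate image
#'
#' Finds the circular dish outline with a circular Hough transform on an edge
#' map, then refines centre and radius by an algebraic least-squares circle
#' fit to the full-resolution edge pixels near the coarse circle. Candidate
#' radii are restricted to `expected_radius_frac * min(H, W)`; among
#' well-supported candidates, ties are broken towards the larger radius and
#' then the more central circle.
#'
#' @param image a [plate_image()] or H x W x 3 array.
#' @param expected_radius_frac length-2 numeric: admissible dish radius as a
#'   fraction of the minimum image dimension.
#' @param diameter_mm physical dish diameter in mm (default 95, a standard
#'   deep-well petri dish); carried through to area calibration.
#' @param min_support minimum fraction of the candidate circle's
#'   circumference that must be covered by edge votes.
#' @param max_detect_dim images are downscaled to at most this many pixels on
#'   the long side for the Hough stage (full resolution is used for the
#'   refinement fit).
#' @param n_theta unused for gradient-directed voting, kept for tuning the
#'   fallback dense voting.
#'
#' @return An object of class `dish_detection`: list with `center_xy`
#'   (0-based, x = column, y = row), `radius_px`, `diameter_mm`, `support`.
#' @export
detect_dish <- function(image, expected_radius_frac = c(0.30, 0.49),
                        diameter_mm = 95, min_support = 0.25,
                        max_detect_dim = 220, n_theta = 48) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  gray <- to_gray(px)
  H <- nrow(gray); W <- ncol(gray)
  stopifnot(length(expected_radius_frac) == 2, diameter_mm > 0)

  r_lo <- expected_radius_frac[1] * min(H, W)
  r_hi <- expected_radius_frac[2] * min(H, W)

  # --- coarse stage on a downscaled copy -------------------------------
  f <- min(1, max_detect_dim / max(H, W))
  iy <- unique(round(seq(1, H, length.out = max(2, round(H * f)))))
  ix <- unique(round(seq(1, W, length.out = max(2, round(W * f)))))
  g <- gray[iy, ix]
  g <- box3(box3(g)) / 81   # smooth for stable gradient directions
  hs <- nrow(g); ws <- ncol(g)
  sy <- (H - 1) / (hs - 1); sx <- (W - 1) / (ws - 1)  # detect px -> full px

  ed <- edge_points(g, thr = 0.04)
  if (nrow(ed) < 10) {
    stop_frondkit("no dish found: image has no circular edge support",
                  "frondkit_no_dish")
  }

  radii <- seq(max(3, r_lo / sx), r_hi / sx, by = 1)
  best <- hough_best_circle(ed, hs, ws, radii, min_support)
  if (is.null(best)) {
    stop_frondkit("no dish found: no circle with sufficient edge support",
                  "frondkit_no_dish")
  }

  cx0 <- (best$cx - 1) * sx; cy0 <- (best$cy - 1) * sy; r0 <- best$r * sx

  # --- refinement: least-squares circle on full-res edge pixels, iterated
  # so the selection band re-centres on the current fit --------------------
  edf <- edge_points(gray, thr = 0.06)
  for (it in 1:3) {
    d <- sqrt(((edf$x - 1) - cx0)^2 + ((edf$y - 1) - cy0)^2)
    band <- abs(d - r0) <= pmax(3, 0.04 * r0)
    if (sum(band) < 20) break
    fit <- fit_circle_kasa((edf$x - 1)[band], (edf$y - 1)[band])
    if (fit$r < r_lo * 0.9 || fit$r > r_hi * 1.1) break
    cx0 <- fit$cx; cy0 <- fit$cy; r0 <- fit$r
  }

  # clamp so the circle lies inside image bounds
  r_fit <- min(r0, cx0, cy0, (W - 1) - cx0, (H - 1) - cy0)
  if (r_fit < r0 - 0.5) {
    warn("detected dish extends beyond the image; radius clamped to bounds")
  }
  structure(
    list(center_xy = c(x = cx0, y = cy0), radius_px = r_fit,
         diameter_mm = diameter_mm, support = best$support),
    class = "dish_detection"
  )
}

#' @export
print.dish_detection <- function(x, ...) {
  cat(sprintf(
    "<dish_detection> centre (%.1f, %.1f) px, radius %.1f px, dish %.1f mm, support %.2f\n",
    x$center_xy[1], x$center_xy[2], x$radius_px, x$diameter_mm, x$support))
  invisible(x)
}

# gradient-magnitude edge pixels with gradient direction; x = col, y = row
edge_points <- function(g, thr = 0.06, max_points = 6000) {
  H <- nrow(g); W <- ncol(g)
  gx <- (g[, c(2:W, W)] - g[, c(1, 1:(W - 1))]) / 2
  gy <- (g[c(2:H, H), ] - g[c(1, 1:(H - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  idx <- which(mag > thr)
  if (length(idx) > max_points) {
    idx <- idx[round(seq(1, length(idx), length.out = max_points))]
  }
  tibble(y = ((idx - 1) %% H) + 1, x = ((idx - 1) %/% H) + 1,
         ux = gx[idx] / mag[idx], uy = gy[idx] / mag[idx])
}

# circular Hough vote in two stages: every edge point votes for candidate
# centres along +/- its gradient direction across the whole radius band
# (centre accumulator), then the radius is read off a histogram of
# edge-to-centre distances. Support = fraction of the circumference covered
# by edge pixels near the circle. Ties among near-equal radius bins are
# broken towards the larger radius, then (among centre cells tied at the
# accumulator maximum) towards the more central one.
hough_best_circle <- function(ed, H, W, radii, min_support) {
  rr <- seq(min(radii), max(radii), by = 1)
  n_e <- nrow(ed)
  cx <- rep(ed$x, 2 * length(rr)) +
    rep(c(-1, 1), each = n_e * length(rr)) *
    rep(rep(rr, each = n_e), 2) * rep(ed$ux, 2 * length(rr))
  cy <- rep(ed$y, 2 * length(rr)) +
    rep(c(-1, 1), each = n_e * length(rr)) *
    rep(rep(rr, each = n_e), 2) * rep(ed$uy, 2 * length(rr))
  ok <- cx >= 1 & cx <= W & cy >= 1 & cy <= H
  if (!any(ok)) return(NULL)
  lin <- (round(cx[ok]) - 1) * H + round(cy[ok])
  A <- box3(box3(matrix(tabulate(lin, nbins = H * W), H, W)))
  mx <- which(A == max(A))
  mcy <- ((mx - 1) %% H) + 1
  mcx <- ((mx - 1) %/% H) + 1
  # tie-break at the accumulator maximum: most central cell
  dc <- (mcx - (W + 1) / 2)^2 + (mcy - (H + 1) / 2)^2
  ctr <- c(mcx[which.min(dc)], mcy[which.min(dc)])

  d <- sqrt((ed$x - ctr[1])^2 + (ed$y - ctr[2])^2)
  d <- d[d >= min(rr) - 2 & d <= max(rr) + 2]
  if (length(d) < 10) return(NULL)
  counts <- map_dbl(rr, function(r) sum(abs(d - r) <= 1.5))
  best_n <- max(counts)
  # near-equal radius bins: prefer the largest radius
  r_best <- max(rr[counts >= 0.9 * best_n])
  support <- sum(abs(d - r_best) <= 2) / (2 * pi * r_best)
  if (support < min_support) return(NULL)
  list(cx = ctr[1], cy = ctr[2], r = r_best, support = min(support, 1))
}

# sum over the 3x3 neighbourhood of every cell (replicated borders)
box3 <- function(A) {
  H <- nrow(A); W <- ncol(A)
  V <- A + A[c(1, 1:(H - 1)), ] + A[c(2:H, H), ]
  V + V[, c(1, 1:(W - 1))] + V[, c(2:W, W)]
}

# algebraic (Kasa) circle fit: x^2 + y^2 = 2 a x + 2 b y + c
fit_circle_kasa <- function(x, y) {
  z <- x^2 + y^2
  co <- coef(lm(z ~ x + y))
  a <- co[["x"]] / 2; b <- co[["y"]] / 2
  r <- sqrt(max(co[["(Intercept)"]] + a^2 + b^2, 0))
  list(cx = a, cy = b, r = r)
}
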