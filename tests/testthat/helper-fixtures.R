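# fixtures built in code; everything is a pure function of its seed

suppressPackageStartupMessages(library(dplyr))

# a plate scene with n random frond blobs
make_scene <- function(seed, size = 800, radius_frac = 0.4375, n_blobs = 6,
                       size_px = c(8, 30), noise_sd = 3 / 255) {
  r <- radius_frac * size
  ctr <- c((size - 1) / 2, (size - 1) / 2)
  scene_spec(size = size, radius_px = r,
             blobs = random_blobs(n_blobs, radius_px = r, center = ctr,
                                  size_px = size_px, seed = seed),
             noise_sd = noise_sd, seed = seed)
}

# a dish reference in image coordinates without running detection
manual_dish <- function(cx, cy, r, diameter_mm = 95) {
  structure(list(center_xy = c(x = cx, y = cy), radius_px = r,
                 diameter_mm = diameter_mm, support = 1),
            class = "dish_detection")
}

# a store pre-loaded with one genotype and one mother dish
seeded_store <- function() {
  store <- inv_store()
  s <- inv_add_sample(store, "Spirodela polyrhiza 7498")
  inv_add_item(store, s$sample_id, created = as.Date("2024-01-01"))
  store
}

# an empty placeholder file standing in for an uploaded photo
touch_image <- function(name = "img.jpg") {
  p <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines("x", p)
  p
}

# rotate an H x W x 3 raster by 90 degrees
rot90_px <- function(px) {
  aperm(px[, dim(px)[2]:1, , drop = FALSE], c(2, 1, 3))
}
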