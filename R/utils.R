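# internal helpers shared across modules

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so generators are pure functions of spec + seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_frondkit <- function(msg, class) {
  abort(msg, class = c(class, "frondkit_error"))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}

is_scalar_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
}

# luminance of an H x W x 3 array in [0, 1]
to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# H x W x 3 array -> hue (degrees 0-360), saturation, value matrices
to_hsv <- function(px) {
  d <- dim(px)
  m <- rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                     as.vector(px[, , 3])), maxColorValue = 1)
  list(h = matrix(m[1, ] * 360, d[1], d[2]),
       s = matrix(m[2, ], d[1], d[2]),
       v = matrix(m[3, ], d[1], d[2]))
}

# hsv (h in degrees) -> length-3 rgb vector in [0, 1]
hsv_to_rgb <- function(h, s, v) {
  as.vector(col2rgb(hsv(h / 360, s, v))) / 255
}

# squared distance of every pixel centre from a point, 0-based (x = col, y = row)
pixel_dist2 <- function(nrow, ncol, cx, cy) {
  dx <- (seq_len(ncol) - 1) - cx
  dy <- (seq_len(nrow) - 1) - cy
  outer(dy^2, dx^2, `+`)
}

# connected-component labelling on a logical matrix (row = y); returns an
# integer matrix of labels (0 = background)
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(lab))
}

# drop connected components smaller than min_px from a logical mask
remove_specks <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}
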