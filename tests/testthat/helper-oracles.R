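# Independent oracles shared across test files. These deliberately avoid the
# package's code paths they are used to check.

# SMIA TV distortion evaluated directly on analytic (ground-truth) corner
# coordinates: vertical extents of outer vs central corner columns.
smia_oracle <- function(x, y) {
  nc <- ncol(y)
  A1 <- max(y[, 1]) - min(y[, 1])
  A2 <- max(y[, nc]) - min(y[, nc])
  mid <- (nc + 1) / 2
  B <- if (mid == floor(mid)) max(y[, mid]) - min(y[, mid]) else
    ((max(y[, floor(mid)]) - min(y[, floor(mid)])) +
       (max(y[, ceiling(mid)]) - min(y[, ceiling(mid)]))) / 2
  100 * ((A1 + A2) / 2 - B) / B
}

# hot-pixel fraction by explicit per-pixel loop (naive counting oracle)
naive_specular <- function(image, thr = 250) {
  px <- image$pixels
  d <- dim(px)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    luma <- 0.299 * px[i, j, 1] + 0.587 * px[i, j, 2] + 0.114 * px[i, j, 3]
    if (luma > thr) n <- n + 1L
  }
  100 * n / (d[1] * d[2])
}

# trapezoid-rule quadrature of intensity * weight on the spectrum grid
trapz_radiance <- function(s, w, scale = 1) {
  f <- s$intensity * scale * w$w(s$wavelength_nm)
  sum(diff(s$wavelength_nm) * (f[-1] + f[-length(f)]) / 2)
}

# build a raster_image from an H x W x 3 numeric array without the generators
make_image <- function(arr, mm_per_px = NULL) {
  raster_image(arr, mm_per_px = mm_per_px)
}

# uniform one-colour frame
flat_image <- function(rgb, h = 16, w = 16, mm_per_px = NULL) {
  raster_image(array(rep(rgb, each = h * w), c(h, w, 3)),
               mm_per_px = mm_per_px)
}

# standard checkerboard scene used by several geometry tests:
# 384 x 384 px at 0.12 mm/px -> 2 mm squares are ~16.7 px
cb_scene <- function(seed = 7) scene_spec(384, 384, seed = seed,
                                          mm_per_px = 0.12)
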