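test_that("USAF conversions reproduce the chart arithmetic", {
  expect_equal(usaf_frequency(0, 1), 1)
  expect_equal(usaf_frequency(1, 1), 2)
  expect_equal(usaf_frequency(4, 4), 2^4.5)
  expect_equal(usaf_line_width_um(0, 1), 500)
  # halving identity across groups, all elements
  for (e in 1:6)
    expect_equal(usaf_line_width_um(3, e), usaf_line_width_um(2, e) / 2)
  expect_error(usaf_frequency(0, 7), "element")
})

test_that("detect_grid recovers generated corners to sub-pixel accuracy", {
  sp <- cb_scene()
  img <- gen_checkerboard(sp, 2, distortion_model(0))
  tr <- attr(img, "truth")
  g <- detect_grid(img, tr$rows, tr$cols, square_mm = 2)
  expect_identical(dim(g$x), dim(tr$x))
  expect_lt(max(sqrt((g$x - tr$x)^2 + (g$y - tr$y)^2)), 0.5)

  # warped grids stay within 0.5 px for |k1| <= 0.2 at the standard target
  # geometry (20 px squares; stronger warps need that sampling headroom)
  sp2 <- scene_spec(480, 480, seed = 7, mm_per_px = 0.1)
  for (k1 in c(-0.2, 0.12)) {
    imgk <- gen_checkerboard(sp2, 2, distortion_model(k1))
    trk <- attr(imgk, "truth")
    gk <- detect_grid(imgk, trk$rows, trk$cols)
    expect_lt(max(sqrt((gk$x - trk$x)^2 + (gk$y - trk$y)^2)), 0.5,
              label = paste("k1 =", k1))
  }

  expect_error(detect_grid(flat_image(c(255, 255, 255), 64, 64), 5, 5),
               "detection error")
})

test_that("detect_grid is canonical under 180-degree rotation", {
  sp <- cb_scene()
  img <- gen_checkerboard(sp, 2, distortion_model(-0.05))
  tr <- attr(img, "truth")
  n <- dim(img$pixels)[1]
  rot <- raster_image(img$pixels[n:1, n:1, , drop = FALSE],
                      mm_per_px = img$mm_per_px)
  g1 <- detect_grid(img, tr$rows, tr$cols)
  g2 <- detect_grid(rot, tr$rows, tr$cols)
  # map rotated detections back into the original frame; ordering must agree
  expect_equal(g1$x, (n - 1) - g2$x[tr$rows:1, tr$cols:1],
               tolerance = 0.05)
  expect_equal(g1$y, (n - 1) - g2$y[tr$rows:1, tr$cols:1],
               tolerance = 0.05)
})

test_that("smia_tv_distortion matches the analytic-corner oracle", {
  # standard target geometry: +/- k1 then yields identical lattice extents,
  # so the magnitude-symmetry comparison is meaningful
  sp <- scene_spec(480, 480, seed = 7, mm_per_px = 0.1)
  percents <- c()
  for (k1 in c(-0.1, -0.05, 0.05, 0.1)) {
    img <- gen_checkerboard(sp, 2, distortion_model(k1))
    tr <- attr(img, "truth")
    d <- smia_tv_distortion(detect_grid(img, tr$rows, tr$cols))
    expect_equal(sign(d$percent), sign(k1), label = paste("k1 =", k1))
    expect_lt(abs(d$percent - smia_oracle(tr$x, tr$y)), 0.1,
              label = paste("k1 =", k1))
    expect_identical(d$label, if (k1 < 0) "barrel" else "pincushion")
    percents <- c(percents, d$percent)
  }
  # |percent| monotone in |k1|, and +/- magnitudes agree within 15%
  expect_gt(abs(percents[1]), abs(percents[2]))
  expect_gt(abs(percents[4]), abs(percents[3]))
  expect_lt(abs(abs(percents[2]) - percents[3]) / percents[3], 0.15)
})

test_that("smia_tv_distortion handles ideal and degenerate grids", {
  # ideal analytic lattice, no image pipeline
  x <- outer(rep(1, 9), seq(10, 90, 10))
  y <- outer(seq(10, 90, 10), rep(1, 9))
  d <- smia_tv_distortion(grid_observation(x, y))
  expect_equal(d$percent, 0)
  expect_identical(d$label, "none")
  expect_error(smia_tv_distortion(
    grid_observation(x[1:3, 1:3], y[1:3, 1:3] * 0 + c(1, 1, 1))),
    "ordered")
})

test_that("diagonal_fov recovers the stated geometry", {
  # 640 x 480 frame, 16 px spacing for 2 mm squares -> 800 px diagonal at
  # 0.125 mm/px = 100 mm
  x <- outer(rep(1, 11), seq(100, 260, 16))
  y <- outer(seq(100, 260, 16), rep(1, 11))
  img <- flat_image(c(255, 255, 255), 480, 640)
  g <- grid_observation(x, y, square_mm = 2)
  fov <- diagonal_fov(g, img)
  expect_equal(as.numeric(fov), 100)
  expect_equal(attr(fov, "mm_per_px"), 0.125)
  # doubled spacing halves the field of view
  g2 <- grid_observation(x * 2, y * 2, square_mm = 2)
  expect_equal(as.numeric(diagonal_fov(g2, img)), 50)
  # anisotropic spacing warns and uses the mean
  g3 <- grid_observation(x * 1.2, y, square_mm = 2)
  expect_warning(f3 <- diagonal_fov(g3, img), "anisotropic")
  expect_equal(attr(f3, "mm_per_px"), 2 / mean(c(16 * 1.2, 16)))
})

test_that("diagonal_fov closes the loop on generated checkerboards", {
  sp <- cb_scene()
  img <- gen_checkerboard(sp, 2, distortion_model(0))
  tr <- attr(img, "truth")
  fov <- diagonal_fov(detect_grid(img, tr$rows, tr$cols, square_mm = 2), img)
  true_fov <- sqrt(384^2 + 384^2) * 0.12
  expect_equal(as.numeric(fov), true_fov, tolerance = 0.01)
})

test_that("magnification is the reference-field ratio", {
  expect_equal(magnification(100, 100), 1)
  expect_equal(magnification(25, 100), 4)
  expect_equal(magnification(50, 100), 2 * magnification(100, 100))
  expect_error(magnification(0, 10), "positive")
})

test_that("michelson contrast separates resolved from blurred bars", {
  sp <- scene_spec(256, 256, mm_per_px = 0.05)
  img <- gen_usaf_bars(sp, 0, 1)
  expect_gt(michelson_contrast(img), 0.9)
  # heavy blur wipes out the contrast of fine bars
  y <- colpoqc:::luma8(img)
  b <- colpoqc:::gauss_blur(y, 12)
  blurred <- raster_image(array(rep(round(b), 3), c(256, 256, 3)))
  roi <- c(39, 102, 89, 152)              # horizontal bar triplet
  expect_lt(michelson_contrast(blurred, roi),
            michelson_contrast(img, roi))
})
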