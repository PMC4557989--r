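test_that("generators are pure functions of (spec, params, seed)", {
  sp <- scene_spec(128, 128, seed = 9, mm_per_px = 0.2)
  a <- gen_checkerboard(sp, 2)
  b <- gen_checkerboard(sp, 2)
  expect_identical(a$pixels, b$pixels)
  expect_identical(gen_color_chart(sp, noise_sd = 2)$pixels,
                   gen_color_chart(sp, noise_sd = 2)$pixels)
  expect_identical(gen_cervix_scene(sp, 2)$pixels,
                   gen_cervix_scene(sp, 2)$pixels)
  # generators must not disturb the session RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(gen_cervix_scene(sp, 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("checkerboard truth corners follow the radial warp model", {
  sp <- cb_scene()
  # identity warp: true corners collinear row-wise
  tr0 <- attr(gen_checkerboard(sp, 2, distortion_model(0)), "truth")
  expect_lt(max(apply(tr0$y, 1, function(r) diff(range(r)))), 1e-9)
  # barrel: outer-edge column heights shrink relative to the centre column
  trb <- attr(gen_checkerboard(sp, 2, distortion_model(-0.05)), "truth")
  expect_lt(smia_oracle(trb$x, trb$y), 0)
  # pincushion mirrors the signature
  trp <- attr(gen_checkerboard(sp, 2, distortion_model(0.05)), "truth")
  expect_gt(smia_oracle(trp$x, trp$y), 0)
  # grid must fit
  expect_error(gen_checkerboard(scene_spec(64, 64, mm_per_px = 0.2), 4),
               "does not fit")
  expect_error(distortion_model(0.6), "0.5")
})

test_that("USAF bars render at the analytic width", {
  tr <- attr(gen_usaf_bars(scene_spec(256, 256, mm_per_px = 0.05), 0, 1),
             "truth")
  expect_equal(tr$width_px, 10)            # 500 um at 50 um/px
  tr2 <- attr(gen_usaf_bars(scene_spec(256, 256, mm_per_px = 0.05), 1, 1),
              "truth")
  expect_equal(tr2$width_px, 5)            # group + 1 halves the width
  tr3 <- attr(gen_usaf_bars(scene_spec(128, 128, mm_per_px = 0.005), 4, 4),
              "truth")
  expect_equal(tr3$width_px, 4.419, tolerance = 1e-3)
  expect_error(gen_usaf_bars(scene_spec(256, 256, mm_per_px = 0.5), 4, 4),
               "under 2 px")
})

test_that("colour chart renders reference Lab values through the cast", {
  sp <- scene_spec(480, 400, seed = 3)
  chart <- gen_color_chart(sp)
  tr <- attr(chart, "truth")
  p <- extract_patches(chart, tr$layout)
  meas <- srgb_to_lab(as.matrix(p[, c("R", "G", "B")]), white = "D50")
  rep0 <- color_error_report(meas, tr$reference[, c("L", "a", "b")])
  expect_lte(rep0$max_dE, 0.5)             # identity up to 8-bit quantization

  # gray cast scaling all channels: lightness carries most of the error
  cast <- diag(3) * 0.8
  p2 <- extract_patches(gen_color_chart(sp, cast = cast), tr$layout)
  rep2 <- color_error_report(
    srgb_to_lab(as.matrix(p2[, c("R", "G", "B")]), white = "D50"),
    tr$reference[, c("L", "a", "b")])
  expect_true(all(rep2$per_patch$dC <= rep2$per_patch$dE))
  expect_lt(rep2$mean_dC, rep2$mean_dE)

  expect_error(gen_color_chart(sp, reference = data.frame(L = 50, a = 0,
                                                          b = 0)),
               "24 .* or 30")
})

test_that("beam profiles have the stated FWHM geometry", {
  sp <- scene_spec(512, 512, seed = 2, mm_per_px = 0.25)
  # flat top: >= half-max pixels form a disc of the nominal diameter
  ft <- luminance(gen_beam(sp, "flat_top", fwhm_mm = 40))
  d_ft <- 2 * sqrt(sum(ft$values >= 0.5) / pi) * 0.25
  expect_equal(d_ft, 40, tolerance = 0.5 / 40)
  # gaussian: profile at r = fwhm/2 equals half the centre value within 1%
  sp_odd <- scene_spec(511, 511, seed = 2, mm_per_px = 0.25)
  gb <- gen_beam(sp_odd, "gaussian", fwhm_mm = 40)
  y <- colpoqc:::luma8(gb)
  centre <- y[256, 256]                   # 0-based (255, 255) = exact centre
  at_half <- y[256, 256 + 20 / 0.25]      # 80 px right = exactly 20 mm
  expect_equal(at_half / centre, 0.5, tolerance = 0.01)
  gb <- gen_beam(sp, "gaussian", fwhm_mm = 40)
  # normalization: peak scaling leaves the half-max disc almost unchanged
  d1 <- beam_fwhm_diameter(luminance(gb))$fwhm_diameter_mm
  d2 <- beam_fwhm_diameter(
    luminance(gen_beam(sp, "gaussian", fwhm_mm = 40,
                       peak = 128)))$fwhm_diameter_mm
  expect_equal(d1, d2, tolerance = 0.02)
  expect_error(gen_beam(sp, "gaussian", fwhm_mm = 130), "exceeds frame")
})

test_that("generated spectra match their stated shapes", {
  sh <- spectrum_peak_fwhm(gen_spectrum("led", centers = 530, fwhms = 30,
                                        amps = 1))
  expect_equal(sh$central_nm, 530, tolerance = 1)
  expect_equal(sh$fwhm_nm, 30, tolerance = 1)

  hal <- gen_spectrum("halogen", temperature_K = 3200)
  expect_gt(hal$intensity[hal$wavelength_nm == 900],
            hal$intensity[hal$wavelength_nm == 450])
  expect_equal(max(hal$intensity), 1)

  lp <- gen_spectrum("filtered", base = hal, filter = "longpass",
                     edges = 500)
  expect_true(all(lp$intensity[lp$wavelength_nm < 495] == 0))
  bp <- gen_spectrum("filtered", base = hal, filter = "bandpass",
                     edges = c(500, 560))
  expect_true(all(bp$intensity[bp$wavelength_nm > 565] == 0))
  expect_error(gen_spectrum("filtered", base = hal, filter = "longpass",
                            edges = 2000), "outside")

  # non-negative and integrable for assorted parameter draws
  for (k in 1:5) {
    s <- gen_spectrum("led", centers = c(430 + 10 * k, 560),
                      fwhms = c(20, 90 + k), amps = c(1, 0.5))
    expect_true(all(s$intensity >= 0) && is.finite(sum(s$intensity)))
  }
})

test_that("cervix scene injects exactly the requested specular pixels", {
  expect_equal(specular_fraction(gen_cervix_scene(scene_spec(200, 200,
                                                             seed = 4), 0)),
               0)
  sc <- gen_cervix_scene(scene_spec(200, 200, seed = 4), 1.0)
  y <- colpoqc:::luma8(sc)
  expect_identical(sum(y > 250), 400L)     # 1% of 200 x 200, exact count
  expect_error(gen_cervix_scene(scene_spec(64, 64), 40), "\\[0, 30\\]")
  green <- gen_cervix_scene(scene_spec(64, 64, seed = 2), green_mode = TRUE)
  expect_gt(mean(green$pixels[, , 2]), mean(green$pixels[, , 1]))
  expect_gt(mean(green$pixels[, , 2]), mean(green$pixels[, , 3]))
})
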