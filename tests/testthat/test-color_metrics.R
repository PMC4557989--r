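test_that("srgb_to_lab matches the standard chain at anchor points", {
  w <- srgb_to_lab(c(255, 255, 255), "D65")
  expect_equal(unname(w[1]), 100, tolerance = 1e-6)
  expect_lt(max(abs(w[2:3])), 0.5)
  expect_equal(unname(srgb_to_lab(c(0, 0, 0), "D65")), c(0, 0, 0),
               tolerance = 1e-6)
  # mid-gray: Y = 0.1841 inverts through the cube-root law to L ~ 50
  g <- srgb_to_lab(c(119, 119, 119), "D65")
  expect_equal(unname(g[1]), 50, tolerance = 1)
  expect_lt(max(abs(g[2:3])), 1e-4)
  # Bradford-adapted D50 keeps white neutral
  w50 <- srgb_to_lab(c(255, 255, 255), "D50")
  expect_equal(unname(w50[1]), 100, tolerance = 1e-6)
  expect_lt(max(abs(w50[2:3])), 0.5)
})

test_that("srgb_to_lab agrees with grDevices::convertColor at D65", {
  set.seed(11)
  rgb <- matrix(sample(0:255, 300, TRUE), ncol = 3)
  mine <- srgb_to_lab(rgb, "D65")
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab",
                                 to.ref.white = "D65")
  expect_lt(max(abs(mine - ref)), 0.5)
})

test_that("lab_to_srgb inverts srgb_to_lab up to quantization", {
  set.seed(12)
  rgb <- matrix(sample(0:255, 300, TRUE), ncol = 3)
  for (wh in c("D50", "D65"))
    expect_lte(max(abs(lab_to_srgb(srgb_to_lab(rgb, wh), wh) - rgb)), 1)
})

test_that("delta metrics follow their definitions", {
  a <- c(50, 10, 10)
  expect_equal(delta_e_ab(a, a), 0)
  expect_equal(delta_e_ab(c(50, 0, 0), c(50, 3, 4)), 5)
  # luminance-only difference: dE = dL, dC = 0
  expect_equal(delta_e_ab(c(55, 2, 3), c(50, 2, 3)), 5)
  expect_equal(delta_c_ab(c(55, 2, 3), c(50, 2, 3)), 0)
  expect_equal(delta_c_ab(c(10, 0, 0), c(90, 3, 4)), 5)
})

test_that("delta_e_ab is a metric and dominates delta_c_ab", {
  set.seed(5)
  n <- 10000
  x <- cbind(runif(n, 0, 100), runif(n, -100, 100), runif(n, -100, 100))
  y <- cbind(runif(n, 0, 100), runif(n, -100, 100), runif(n, -100, 100))
  z <- cbind(runif(n, 0, 100), runif(n, -100, 100), runif(n, -100, 100))
  dE <- delta_e_ab(x, y)
  expect_true(all(dE >= delta_c_ab(x, y)))
  eq <- abs(x[, 1] - y[, 1]) < 1e-12
  expect_equal(dE[eq], delta_c_ab(x, y)[eq])
  expect_equal(dE, delta_e_ab(y, x))                       # symmetry
  expect_true(all(dE <= delta_e_ab(x, z) + delta_e_ab(z, y) + 1e-9))
})

test_that("extract_patches means are exact on noiseless charts", {
  sp <- scene_spec(480, 400, seed = 3)
  chart <- gen_color_chart(sp)
  tr <- attr(chart, "truth")
  p <- extract_patches(chart, tr$layout)
  expect_equal(as.matrix(p[, c("R", "G", "B")]), unname(tr$fills),
               ignore_attr = TRUE)
  # uniform patches: inset does not matter
  p2 <- extract_patches(chart, tr$layout, inset = 0.45)
  expect_equal(p[, c("R", "G", "B")], p2[, c("R", "G", "B")])
  expect_error(extract_patches(chart, c(60, 60)), "under 8 px")
})

test_that("patch means under noise stay within the standard error", {
  sp <- scene_spec(480, 400, seed = 31)
  chart <- gen_color_chart(sp, noise_sd = 2)
  tr <- attr(chart, "truth")
  p <- extract_patches(chart, tr$layout)
  # central 50% x 50% of an 80 x 80 cell -> n = 1600, se = 2 / 40 = 0.05
  npx <- (0.5 * 480 / 6) * (0.5 * 400 / 5)
  tol <- 3 * 2 / sqrt(npx) + 0.1          # + clipping/rounding allowance
  expect_lt(max(abs(as.matrix(p[, c("R", "G", "B")]) - tr$fills)), tol)
})

test_that("color_error_report aggregates per-patch differences", {
  ref <- data.frame(L = c(50, 70), a = c(10, -5), b = c(0, 20))
  expect_equal(color_error_report(ref, ref)$max_dE, 0)
  one <- color_error_report(data.frame(L = 55, a = 0, b = 0),
                            data.frame(L = 50, a = 0, b = 0))
  expect_equal(one$mean_dE, 5)
  expect_equal(one$max_dE, 5)
  expect_equal(one$mean_dC, 0)
  # brute-force agreement on a cast chart
  set.seed(7)
  meas <- as.matrix(ref) + matrix(rnorm(6), 2)
  rep2 <- color_error_report(meas, ref)
  byhand <- sapply(1:2, function(i) sqrt(sum((meas[i, ] - ref[i, ])^2)))
  expect_equal(rep2$per_patch$dE, byhand)
  expect_equal(rep2$mean_dE, mean(byhand))
  expect_error(color_error_report(ref[0, ], ref[0, ]), "empty")
})

test_that("match_color is an identity when source equals reference", {
  src <- gen_cervix_scene(scene_spec(96, 96, seed = 5))
  roi <- c(10, 10, 85, 85)
  out <- match_color(src, roi, src, roi)
  expect_lte(max(abs(out$pixels - src$pixels)), 1)
})

test_that("match_color cancels a pure Lab lightness shift", {
  src <- gen_cervix_scene(scene_spec(96, 96, seed = 5))
  lab <- colpoqc:::image_to_lab(src)
  lab[, 1] <- pmin(100, lab[, 1] + 10)
  rgb <- lab_to_srgb(lab)
  arr <- array(0L, dim(src$pixels))
  for (ch in 1:3) arr[, , ch] <- rgb[, ch]
  ref <- raster_image(arr)
  roi <- c(10, 10, 85, 85)
  out <- match_color(src, roi, ref, roi)
  out_lab <- colpoqc:::image_to_lab(out)
  ref_lab <- colpoqc:::image_to_lab(ref)
  expect_lt(abs(mean(out_lab[, 1]) - mean(ref_lab[, 1])), 0.5)
  # mean-matching by construction: ROI-mean distance shrinks
  pre <- delta_e_ab(colMeans(colpoqc:::image_to_lab(src)),
                    colMeans(ref_lab))
  post <- delta_e_ab(colMeans(out_lab), colMeans(ref_lab))
  expect_lt(post, pre)
})

test_that("match_color recovers a general affine Lab cast", {
  src <- gen_cervix_scene(scene_spec(96, 96, seed = 8))
  lab <- colpoqc:::image_to_lab(src)
  cast <- sweep(lab, 2, c(1.1, 0.8, 0.9), `*`)
  cast[, 1] <- pmin(100, cast[, 1] + 5)
  rgb <- lab_to_srgb(cast)
  arr <- array(0L, dim(src$pixels))
  for (ch in 1:3) arr[, , ch] <- rgb[, ch]
  ref <- raster_image(arr)
  roi <- c(5, 5, 90, 90)
  out <- match_color(src, roi, ref, roi)
  m <- colMeans(colpoqc:::image_to_lab(out))
  r <- colMeans(colpoqc:::image_to_lab(ref))
  expect_lt(delta_e_ab(m, r), 1.0)
})

test_that("zero-variance source channels are shifted by mean only", {
  flat <- flat_image(c(120, 120, 120), 64, 64)
  tex <- gen_cervix_scene(scene_spec(64, 64, seed = 3))
  roi <- c(0, 0, 63, 63)                  # whole frame
  out <- match_color(flat, roi, tex, roi)
  out_lab <- colpoqc:::image_to_lab(out)
  ref_lab <- colpoqc:::image_to_lab(tex)
  expect_lt(max(abs(colMeans(out_lab) - colMeans(ref_lab))), 1)
})

test_that("bundled chart reference is valid and clearly synthetic", {
  ref <- default_chart_reference()
  expect_identical(nrow(ref), 30L)
  expect_false(anyDuplicated(ref$patch_id) > 0)
  expect_true(all(ref$L >= 0 & ref$L <= 100))
  path <- system.file("extdata", "colorchart_synthetic_lab.csv",
                      package = "colpoqc")
  expect_match(paste(readLines(path, n = 4), collapse = " "),
               "SYNTHETIC", ignore.case = FALSE)
})
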