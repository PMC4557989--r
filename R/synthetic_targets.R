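# Deterministic, seeded generators for every input class the metric modules
# consume: warped checkerboards, USAF-1951 bar targets, colour charts, beam
# profiles, LED/halogen/filtered spectra and cervix-like scenes.

#' Scene specification for synthetic targets
#'
#' @param width_px,height_px frame size in pixels (both >= 64).
#' @param seed integer random seed; every generator is a pure function of
#'   (spec, params, seed) with no global RNG state left behind.
#' @param mm_per_px physical scale, mm per pixel.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, seed = 1L, mm_per_px = NULL) {
  if (width_px < 64 || height_px < 64)
    stop("scene dimensions must be at least 64 px")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 seed = as.integer(seed), mm_per_px = mm_per_px),
            class = "scene_spec")
}

#' Single-coefficient radial distortion model
#'
#' Brown model with one coefficient: a point at normalized radius r from the
#' principal point maps to r' = r (1 + k1 r^2), with r normalized to the
#' half-diagonal. Negative k1 gives barrel distortion, positive pincushion.
#'
#' @param k1 radial coefficient, |k1| <= 0.5.
#' @param center principal point in normalized image coordinates.
#' @return An object of class `distortion_model`.
#' @export
distortion_model <- function(k1 = 0, center = c(0.5, 0.5)) {
  if (abs(k1) > 0.5) stop("|k1| must be <= 0.5 (generator validity range)")
  if (length(center) != 2L || any(center <= 0) || any(center >= 1))
    stop("center must be two normalized coordinates in (0, 1)")
  structure(list(k1 = k1, center = center), class = "distortion_model")
}

# forward warp: ideal (undistorted) pixel coords -> rendered coords.
# x, y are 0-based pixel coordinates; cx, cy principal point; hd half-diagonal.
warp_forward <- function(x, y, cx, cy, hd, k1) {
  dx <- x - cx; dy <- y - cy
  f <- 1 + k1 * (dx * dx + dy * dy) / hd^2
  list(x = cx + dx * f, y = cy + dy * f)
}

# inverse warp by damped fixed-point iteration on the normalized radius
warp_inverse_factor <- function(rho_d, k1, iters = 40L) {
  rho <- rho_d
  for (i in seq_len(iters)) rho <- rho_d / (1 + k1 * rho * rho)
  ifelse(rho_d > 0, rho / rho_d, 1)
}

# run code under a private, restored RNG state (Mersenne-Twister, fixed kinds)
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a radially warped checkerboard target
#'
#' Renders a black/white checkerboard of `square_mm` squares, warped by the
#' given radial distortion model (see [distortion_model()]), with supersampled
#' antialiasing. The true (warped) corner coordinates are attached as ground
#' truth for oracle use.
#'
#' @param spec a [scene_spec()]; `mm_per_px` must be set.
#' @param square_mm physical square size (the field-standard target is 2 mm).
#' @param model a [distortion_model()].
#' @param supersample linear supersampling factor for antialiasing.
#' @return A [raster_image()] with attribute `truth`: a list with warped
#'   corner coordinate matrices `x`, `y` (0-based pixel coordinates,
#'   `rows` x `cols`), the ideal coordinates `x_ideal`, `y_ideal`,
#'   `square_px`, and the model.
#' @export
gen_checkerboard <- function(spec, square_mm = 2, model = distortion_model(0),
                             supersample = 5L) {
  stopifnot(inherits(spec, "scene_spec"), inherits(model, "distortion_model"))
  if (is.null(spec$mm_per_px)) stop("spec$mm_per_px is required")
  if (square_mm <= 0) stop("square_mm must be positive")
  W <- spec$width_px; H <- spec$height_px
  s <- square_mm / spec$mm_per_px            # square size in px
  if (floor(W / s) < 6 || floor(H / s) < 6)
    stop("grid does not fit: need at least 6 x 6 full squares in the frame")
  cx <- model$center[1] * (W - 1); cy <- model$center[2] * (H - 1)
  hd <- 0.5 * sqrt(W^2 + H^2)
  k1 <- model$k1

  # render: for each (supersampled) output position, pull back through the
  # inverse warp and sample the ideal infinite checkerboard
  ss <- as.integer(supersample)
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- matrix(0, H, W)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  for (oy in off) {
    dy <- (ys + oy) - cy
    for (ox in off) {
      dx <- (xs + ox) - cx
      rho_d <- sqrt(outer(dy * dy, dx * dx, `+`)) / hd
      fac <- warp_inverse_factor(rho_d, k1)
      xi <- cx + outer(rep(1, H), dx) * fac
      yi <- cy + outer(dy, rep(1, W)) * fac
      parity <- (floor((xi - cx) / s) + floor((yi - cy) / s)) %% 2
      acc <- acc + parity
    }
  }
  g <- round(255 * acc / ss^2)
  img <- raster_image(array(rep(g, 3L), c(H, W, 3L)),
                      mm_per_px = spec$mm_per_px)

  # ground-truth corner lattice: anchored at the principal point, largest
  # symmetric rectangle whose warped corners stay inside a safety margin
  margin <- max(4, 0.4 * s)
  imax <- floor((min(cx, W - 1 - cx) - margin) / s)
  jmax <- floor((min(cy, H - 1 - cy) - margin) / s)
  ok <- function(im, jm) {
    w <- warp_forward(cx + im * s, cy + jm * s, cx, cy, hd, k1)
    w$x >= margin && w$x <= W - 1 - margin &&
      w$y >= margin && w$y <= H - 1 - margin
  }
  while (imax >= 1 && jmax >= 1 && !ok(imax, jmax)) {
    if (imax * s >= jmax * s) imax <- imax - 1 else jmax <- jmax - 1
  }
  if (imax < 1 || jmax < 1) stop("grid does not fit after warping")
  ii <- -imax:imax; jj <- -jmax:jmax
  xi <- outer(rep(1, length(jj)), cx + ii * s)   # rows x cols
  yi <- outer(cy + jj * s, rep(1, length(ii)))
  w <- warp_forward(xi, yi, cx, cy, hd, k1)
  attr(img, "truth") <- list(x = w$x, y = w$y, x_ideal = xi, y_ideal = yi,
                             rows = length(jj), cols = length(ii),
                             square_px = s, square_mm = square_mm,
                             model = model)
  img
}

#' Generate a USAF-1951 three-bar element
#'
#' Renders the standard pattern for one (group, element): three horizontal
#' and three vertical bars of width 500 / 2^(group + (element - 1) / 6)
#' micrometres at the stated physical scale, bar length five times the width,
#' black on white, with analytic coverage antialiasing.
#'
#' @param spec a [scene_spec()]; `mm_per_px` must be set.
#' @param group integer group in \[-2, 7\].
#' @param element integer element in \[1, 6\].
#' @return A [raster_image()] with attribute `truth` (bar width in px and um,
#'   spatial frequency in lp/mm, and bar bounding boxes).
#' @export
gen_usaf_bars <- function(spec, group, element) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$mm_per_px)) stop("spec$mm_per_px is required")
  if (group < -2 || group > 7) stop("group must be in [-2, 7]")
  if (!element %in% 1:6) stop("element must be in [1, 6]")
  f <- 2^(group + (element - 1) / 6)           # lp/mm
  w_um <- 500 / f
  w_px <- (w_um / 1000) / spec$mm_per_px
  if (w_px < 2)
    stop(sprintf(paste0("bar width %.2f px is under 2 px at %.4g mm/px; ",
                        "use a finer scale"), w_px, spec$mm_per_px))
  W <- spec$width_px; H <- spec$height_px
  len <- 5 * w_px
  if (len > 0.45 * W || 5 * w_px > 0.9 * H)
    stop("bars do not fit in the frame; enlarge the frame or refine scale")
  g <- matrix(255, H, W)
  cyf <- (H - 1) / 2
  # analytic pixel coverage of an axis-aligned rectangle
  cover1d <- function(coords, a, b)
    pmax(0, pmin(coords + 0.5, b) - pmax(coords - 0.5, a))
  draw_rect <- function(x0, x1, y0, y1) {
    cvx <- cover1d(0:(W - 1), x0, x1)
    cvy <- cover1d(0:(H - 1), y0, y1)
    g <<- g * (1 - outer(cvy, cvx))
  }
  boxes <- list()
  # three horizontal bars, left half
  hx0 <- W / 4 - len / 2
  top <- cyf - 2.5 * w_px
  for (k in 0:2) {
    y0 <- top + 2 * k * w_px
    draw_rect(hx0, hx0 + len, y0, y0 + w_px)
    boxes[[length(boxes) + 1]] <- c(x0 = hx0, x1 = hx0 + len,
                                    y0 = y0, y1 = y0 + w_px)
  }
  # three vertical bars, right half
  vy0 <- cyf - len / 2
  left <- 3 * W / 4 - 2.5 * w_px
  for (k in 0:2) {
    x0 <- left + 2 * k * w_px
    draw_rect(x0, x0 + w_px, vy0, vy0 + len)
    boxes[[length(boxes) + 1]] <- c(x0 = x0, x1 = x0 + w_px,
                                    y0 = vy0, y1 = vy0 + len)
  }
  g <- round(g)
  img <- raster_image(array(rep(g, 3L), c(H, W, 3L)),
                      mm_per_px = spec$mm_per_px)
  attr(img, "truth") <- list(group = group, element = element,
                             freq_lp_mm = f, width_um = w_um, width_px = w_px,
                             boxes = do.call(rbind, boxes))
  img
}

#' Generate a colour chart with known reference CIELAB patch values
#'
#' Each patch is filled with the sRGB rendering of its reference Lab value
#' (D50 reference white, Bradford-adapted), optionally pushed through a 3 x 3
#' linear-RGB cast matrix and perturbed by seeded Gaussian noise.
#'
#' @param spec a [scene_spec()].
#' @param reference data frame with columns `patch_id`, `L`, `a`, `b`; 24
#'   (6 x 4) or 30 (6 x 5) patches. Default: the bundled synthetic,
#'   non-certified 30-patch chart (see [default_chart_reference()]).
#' @param cast 3 x 3 matrix applied to linear RGB channels (identity = no
#'   cast).
#' @param noise_sd Gaussian noise standard deviation on the 8-bit scale.
#' @return A [raster_image()] with attribute `truth` (patch bounding boxes,
#'   fill RGB values, reference Lab, layout).
#' @export
gen_color_chart <- function(spec, reference = default_chart_reference(),
                            cast = diag(3), noise_sd = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(reference)
  layout <- if (n == 24L) c(4L, 6L) else if (n == 30L) c(5L, 6L) else
    stop("reference must have 24 (6x4) or 30 (6x5) patches, got ", n)
  if (!all(c("L", "a", "b") %in% names(reference)))
    stop("reference needs columns L, a, b")
  cast <- as.matrix(cast)
  if (!identical(dim(cast), c(3L, 3L))) stop("cast must be a 3 x 3 matrix")
  W <- spec$width_px; H <- spec$height_px
  nr <- layout[1]; nc <- layout[2]
  if (W %/% nc < 8 || H %/% nr < 8) stop("cells under 8 px; enlarge frame")

  lin <- lab_to_linear_rgb(as.matrix(reference[, c("L", "a", "b")]),
                           white = "D50")
  lin <- clamp01(lin %*% t(cast))
  fills <- round(srgb_encode(lin) * 255)

  px <- array(0L, c(H, W, 3L))
  xb <- round(seq(0, W, length.out = nc + 1))
  yb <- round(seq(0, H, length.out = nr + 1))
  boxes <- data.frame(patch_id = character(n), row = integer(n),
                      col = integer(n), x0 = integer(n), x1 = integer(n),
                      y0 = integer(n), y1 = integer(n),
                      stringsAsFactors = FALSE)
  ids <- if ("patch_id" %in% names(reference)) as.character(reference$patch_id)
         else sprintf("P%02d", seq_len(n))
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    k <- k + 1L
    rows <- (yb[r] + 1):yb[r + 1]; cols <- (xb[cc] + 1):xb[cc + 1]
    for (ch in 1:3) px[rows, cols, ch] <- fills[k, ch]
    boxes[k, ] <- list(ids[k], r, cc, xb[cc], xb[cc + 1] - 1L,
                       yb[r], yb[r + 1] - 1L)
  }
  if (noise_sd > 0) {
    px <- with_seed(spec$seed, {
      px + array(stats::rnorm(length(px), 0, noise_sd), dim(px))
    })
    px <- round(array(pmin(255, pmax(0, px)), dim(px)))
  }
  img <- raster_image(px, mm_per_px = spec$mm_per_px)
  attr(img, "truth") <- list(boxes = boxes, fills = fills,
                             reference = reference, layout = layout,
                             cast = cast, noise_sd = noise_sd)
  img
}

#' Generate a beam profile image on a virtual diffuser
#'
#' Radially symmetric gray-scale profile: `gaussian` uses
#' sigma = fwhm_mm / 2.3548; `flat_top` is a disc of diameter `fwhm_mm` with
#' a 1-px soft edge. An optional centimetre-style grid of dark lines can be
#' overlaid for scale calibration.
#'
#' @param spec a [scene_spec()]; `mm_per_px` must be set.
#' @param shape `"gaussian"` or `"flat_top"`.
#' @param fwhm_mm full width at half maximum of the beam, mm.
#' @param peak peak 8-bit intensity at the beam centre.
#' @param grid_pitch_mm if non-NULL, overlay dark grid lines at this pitch.
#' @return A [raster_image()] with attribute `truth`.
#' @export
gen_beam <- function(spec, shape = c("gaussian", "flat_top"), fwhm_mm,
                     peak = 255, grid_pitch_mm = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- match.arg(shape)
  if (is.null(spec$mm_per_px)) stop("spec$mm_per_px is required")
  W <- spec$width_px; H <- spec$height_px; mpp <- spec$mm_per_px
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  if (fwhm_mm > 0.9 * min(W, H) * mpp)
    stop("beam exceeds frame: fwhm ", fwhm_mm, " mm in a ",
         round(min(W, H) * mpp, 1), " mm frame")
  if (peak < 1 || peak > 255) stop("peak must be in [1, 255]")
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  r_mm <- sqrt(outer(((0:(H - 1)) - cy)^2, ((0:(W - 1)) - cx)^2, `+`)) * mpp
  g <- if (shape == "gaussian") {
    sigma <- fwhm_mm / 2.3548
    peak * exp(-r_mm^2 / (2 * sigma^2))
  } else {
    R <- fwhm_mm / 2
    edge <- mpp            # 1-px linear soft edge
    peak * clamp01((R + edge / 2 - r_mm) / edge)
  }
  if (!is.null(grid_pitch_mm)) {
    if (grid_pitch_mm <= 3 * mpp) stop("grid pitch too fine for this scale")
    dx <- abs(((outer(rep(1, H), (0:(W - 1)) - cx) * mpp + grid_pitch_mm / 2)
               %% grid_pitch_mm) - grid_pitch_mm / 2)
    dy <- abs(((outer((0:(H - 1)) - cy, rep(1, W)) * mpp + grid_pitch_mm / 2)
               %% grid_pitch_mm) - grid_pitch_mm / 2)
    line <- (dx < mpp) | (dy < mpp)   # lines ~2 px wide
    g[line] <- g[line] * 0.25
  }
  g <- round(g)
  img <- raster_image(array(rep(g, 3L), c(H, W, 3L)), mm_per_px = mpp)
  attr(img, "truth") <- list(shape = shape, fwhm_mm = fwhm_mm, peak = peak,
                             grid_pitch_mm = grid_pitch_mm)
  img
}

#' Generate an emission spectrum (LED, halogen or filtered)
#'
#' All spectra are sampled on a 300-1100 nm grid at 1-nm steps, relative
#' units. `led` is a sum of Gaussian peaks (a white LED is the classic blue
#' 450 nm die plus a broad phosphor band near 550 nm); `halogen` is a Planck
#' blackbody curve normalized to unit peak; `filtered` multiplies a base
#' spectrum by an ideal long-pass/short-pass/band-pass transmission with a
#' 5-nm linear roll-off.
#'
#' @param kind `"led"`, `"halogen"` or `"filtered"`.
#' @param centers,fwhms,amps LED peak parameters (vectors, recycled to the
#'   longest). Defaults give a 5000K-class white LED.
#' @param temperature_K halogen filament colour temperature.
#' @param base base [emission_spectrum()] for `kind = "filtered"`.
#' @param filter `"longpass"`, `"shortpass"` or `"bandpass"`.
#' @param edges filter edge wavelength(s), nm: one value for long/short-pass,
#'   two for band-pass.
#' @return An [emission_spectrum()] in relative units.
#' @export
gen_spectrum <- function(kind = c("led", "halogen", "filtered"),
                         centers = c(450, 550), fwhms = c(25, 110),
                         amps = c(1, 0.65), temperature_K = 3200,
                         base = NULL,
                         filter = c("longpass", "shortpass", "bandpass"),
                         edges = NULL) {
  kind <- match.arg(kind)
  wl <- 300:1100
  if (kind == "led") {
    m <- max(length(centers), length(fwhms), length(amps))
    centers <- rep_len(centers, m); fwhms <- rep_len(fwhms, m)
    amps <- rep_len(amps, m)
    if (any(fwhms <= 0)) stop("LED fwhms must be positive")
    it <- rep(0, length(wl))
    for (i in seq_len(m)) {
      sigma <- fwhms[i] / 2.3548
      it <- it + amps[i] * exp(-(wl - centers[i])^2 / (2 * sigma^2))
    }
    return(emission_spectrum(wl, it, delta_lambda_nm = 1))
  }
  if (kind == "halogen") {
    if (temperature_K <= 0) stop("temperature_K must be positive")
    lm <- wl * 1e-9
    h <- 6.62607015e-34; c0 <- 299792458; kb <- 1.380649e-23
    it <- 1 / (lm^5 * (exp(h * c0 / (lm * kb * temperature_K)) - 1))
    return(emission_spectrum(wl, it / max(it), delta_lambda_nm = 1))
  }
  # filtered
  filter <- match.arg(filter)
  if (is.null(base)) stop("kind = 'filtered' requires a base spectrum")
  stopifnot(inherits(base, "emission_spectrum"))
  need <- if (filter == "bandpass") 2L else 1L
  if (is.null(edges) || length(edges) != need)
    stop("filter '", filter, "' needs ", need, " edge wavelength(s)")
  rng <- range(base$wavelength_nm)
  if (any(edges < rng[1]) || any(edges > rng[2]))
    stop("filter edges outside the spectral grid [", rng[1], ", ", rng[2],
         "] nm")
  roll <- 5
  ramp_up <- function(wl, e) pmin(1, pmax(0, (wl - (e - roll / 2)) / roll))
  tr <- switch(filter,
               longpass  = ramp_up(base$wavelength_nm, edges[1]),
               shortpass = 1 - ramp_up(base$wavelength_nm, edges[1]),
               bandpass  = ramp_up(base$wavelength_nm, min(edges)) *
                           (1 - ramp_up(base$wavelength_nm, max(edges))))
  emission_spectrum(base$wavelength_nm, base$intensity * tr,
                    units = base$units,
                    delta_lambda_nm = base$delta_lambda_nm)
}

#' Generate a cervix-like scene with an injectable specular fraction
#'
#' A pink ellipse (ecto-cervix) with a darker os and branching vessel strokes
#' on a dark background; exactly `round(specular_fraction / 100 * H * W)`
#' seeded pixels are set to pure white (255, 255, 255). Base (non-specular)
#' pixels are kept below the hot-pixel luma threshold by construction, so the
#' injected count is the exact ground truth for the specular metric.
#'
#' @param spec a [scene_spec()].
#' @param specular_fraction percentage of pixels to saturate, in \[0, 30\].
#' @param green_mode render through a green-channel-dominant palette (green
#'   field illumination look).
#' @return A [raster_image()] with attribute `truth` (`n_specular`,
#'   `specular_fraction`).
#' @export
gen_cervix_scene <- function(spec, specular_fraction = 0, green_mode = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (specular_fraction < 0 || specular_fraction > 30)
    stop("specular_fraction must be in [0, 30]")
  W <- spec$width_px; H <- spec$height_px
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- outer(rep(1, H), 0:(W - 1)); ys <- outer(0:(H - 1), rep(1, W))
  img <- with_seed(spec$seed, {
    r <- array(70L, c(H, W)); g <- array(40L, c(H, W)); b <- array(45L, c(H, W))
    # ecto-cervix: pink ellipse with mild radial shading
    ax <- 0.40 * W; ay <- 0.38 * H
    d2 <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2
    inside <- d2 <= 1
    shade <- 1 - 0.25 * pmin(1, d2)
    r[inside] <- round(225 * shade[inside])
    g[inside] <- round(150 * shade[inside])
    b[inside] <- round(160 * shade[inside])
    # os: darker central ellipse
    os <- (((xs - cx) / (0.07 * W))^2 + ((ys - cy) / (0.10 * H))^2) <= 1
    r[os] <- 140L; g[os] <- 55L; b[os] <- 70L
    # branching vessels: random walks radiating from the os
    nves <- 14L
    for (v in seq_len(nves)) {
      ang <- stats::runif(1, 0, 2 * pi)
      px0 <- cx + cos(ang) * 0.10 * W; py0 <- cy + sin(ang) * 0.10 * H
      nstep <- 25L + sample.int(30L, 1)
      for (sdx in seq_len(nstep)) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        px0 <- px0 + 1.6 * cos(ang); py0 <- py0 + 1.6 * sin(ang)
        ix <- round(px0); iy <- round(py0)
        if (ix < 1 || ix > W - 2 || iy < 1 || iy > H - 2) break
        if (((ix - cx) / ax)^2 + ((iy - cy) / ay)^2 > 0.95) break
        sel <- cbind(iy + c(0, 1, 0, 1), ix + c(0, 0, 1, 1)) + 1L
        r[sel] <- 150L; g[sel] <- 45L; b[sel] <- 55L
      }
    }
    if (green_mode) {
      y <- 0.299 * r + 0.587 * g + 0.114 * b
      r <- round(0.20 * y); g <- round(0.95 * y); b <- round(0.25 * y)
    }
    # inject exactly n saturated specular pixels, preferentially on tissue
    n <- round(specular_fraction / 100 * H * W)
    if (n > 0) {
      pool <- which(inside & !os)
      if (length(pool) < n) pool <- seq_len(H * W)
      sel <- sample(pool, n)
      r[sel] <- 255L; g[sel] <- 255L; b[sel] <- 255L
    }
    px <- array(0L, c(H, W, 3L))
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
    px
  })
  out <- raster_image(img, mm_per_px = spec$mm_per_px)
  attr(out, "truth") <- list(
    n_specular = round(specular_fraction / 100 * H * W),
    specular_fraction = specular_fraction, green_mode = green_mode)
  out
}
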