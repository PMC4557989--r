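# CIELAB colour-reproduction error against a calibrated chart, and the
# Lab-statistics colour-matching correction used to harmonize captures from
# different devices. Conversion chain: sRGB (IEC 61966-2-1) <-> XYZ with
# Bradford chromatic adaptation <-> CIELAB.

.M_RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     3, 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
# Bradford adaptation between the sRGB native white (D65) and D50
.M_D65_D50 <- matrix(c(1.0478112, 0.0228866, -0.0501270,
                       0.0295424, 0.9904844, -0.0170491,
                      -0.0092345, 0.0150436,  0.7521316),
                     3, 3, byrow = TRUE)
.M_D50_D65 <- solve(.M_D65_D50)
.WHITES <- list(D65 = c(0.95047, 1.0, 1.08883),
                D50 = c(0.96422, 1.0, 0.82521))

# clamp to [0, 1] preserving dim attributes (pmin/pmax with a scalar first
# argument would drop them)
clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

srgb_decode <- function(v) ifelse(v <= 0.04045, v / 12.92,
                                  ((v + 0.055) / 1.055)^2.4)
srgb_encode <- function(v) {
  v <- clamp01(v)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3) stop("rgb must be a length-3 vector or an n x 3 matrix")
  rgb
}

xyz_to_lab <- function(xyz, white) {
  wp <- .WHITES[[white]]
  ft <- lab_f(sweep(xyz, 2, wp, `/`))
  cbind(L = 116 * ft[, 2] - 16,
        a = 500 * (ft[, 1] - ft[, 2]),
        b = 200 * (ft[, 2] - ft[, 3]))
}

lab_to_xyz <- function(lab, white) {
  wp <- .WHITES[[white]]
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  sweep(cbind(lab_finv(fx), lab_finv(fy), lab_finv(fz)), 2, wp, `*`)
}

# Lab (given white) -> linear sRGB (D65 primaries), unclipped
lab_to_linear_rgb <- function(lab, white = "D50") {
  xyz <- lab_to_xyz(as_rgb_matrix(lab), white)
  if (white == "D50") xyz <- xyz %*% t(.M_D50_D65)
  xyz %*% t(.M_XYZ2RGB)
}

#' Convert 8-bit sRGB to CIELAB
#'
#' Standard chain: gamma expansion, linear RGB to XYZ (D65 primaries),
#' Bradford adaptation to the requested reference white, then CIELAB. Chart
#' work in this package defaults to D50 because calibrated targets are imaged
#' under D50/5000K illumination.
#'
#' @param rgb length-3 vector or n x 3 matrix of 8-bit values in \[0, 255\].
#' @param white reference white, `"D50"` (default) or `"D65"`.
#' @return For a single triple, a named numeric vector `(L, a, b)`; for a
#'   matrix input, an n x 3 matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb, white = c("D50", "D65")) {
  white <- match.arg(white)
  single <- is.null(dim(rgb))
  rgb <- as_rgb_matrix(rgb)
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stop("rgb values must lie in [0, 255]")
  xyz <- srgb_decode(rgb / 255) %*% t(.M_RGB2XYZ)
  if (white == "D50") xyz <- xyz %*% t(.M_D65_D50)
  lab <- xyz_to_lab(xyz, white)
  if (single) c(L = lab[1, 1], a = lab[1, 2], b = lab[1, 3]) else lab
}

#' Convert CIELAB to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut values are clipped in linear RGB.
#'
#' @param lab length-3 vector or n x 3 matrix of `(L, a, b)` values.
#' @param white reference white the Lab values are expressed against.
#' @return 8-bit sRGB values, same shape convention as [srgb_to_lab()].
#' @export
lab_to_srgb <- function(lab, white = c("D50", "D65")) {
  white <- match.arg(white)
  single <- is.null(dim(lab))
  lin <- clamp01(lab_to_linear_rgb(as_rgb_matrix(lab), white))
  rgb <- round(srgb_encode(lin) * 255)
  if (single) c(R = rgb[1, 1], G = rgb[1, 2], B = rgb[1, 3]) else rgb
}

as_lab_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("L", "a", "b")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x
}

#' CIELAB colour differences
#'
#' `delta_e_ab()` is the Euclidean distance in (L*, a*, b*); `delta_c_ab()`
#' omits the lightness axis, so it ignores pure luminance differences.
#' Always `delta_e_ab(x, y) >= delta_c_ab(x, y)`, with equality iff
#' `dL = 0`.
#'
#' @param x,y Lab triples (length-3 vectors) or n x 3 matrices, compared
#'   row-wise.
#' @return Numeric colour difference(s).
#' @export
delta_e_ab <- function(x, y) {
  x <- as_lab_matrix(x); y <- as_lab_matrix(y)
  sqrt(rowSums((x - y)^2))
}

#' @rdname delta_e_ab
#' @export
delta_c_ab <- function(x, y) {
  x <- as_lab_matrix(x); y <- as_lab_matrix(y)
  sqrt(rowSums((x[, 2:3, drop = FALSE] - y[, 2:3, drop = FALSE])^2))
}

#' Sample mean patch colours from a chart image
#'
#' The frame is divided into a `layout` grid of cells; each patch is sampled
#' over its central region after insetting a fraction of the cell on every
#' side, to stay clear of patch borders.
#'
#' @param image a [raster_image()] of a chart filling the frame.
#' @param layout integer vector `c(rows, cols)` of the patch grid.
#' @param inset fraction of each cell trimmed from every side (default 0.25,
#'   i.e. the central 50% x 50% region is averaged).
#' @return Data frame with `row`, `col`, and mean `R`, `G`, `B` per patch,
#'   in row-major patch order.
#' @export
extract_patches <- function(image, layout, inset = 0.25) {
  stopifnot(inherits(image, "raster_image"))
  if (length(layout) != 2L || any(layout < 1))
    stop("layout must be c(rows, cols)")
  if (inset < 0 || inset >= 0.5) stop("inset must be in [0, 0.5)")
  d <- dim(image$pixels); H <- d[1]; W <- d[2]
  nr <- layout[1]; nc <- layout[2]
  if (W %/% nc < 8 || H %/% nr < 8)
    stop("layout inconsistent with frame: cells under 8 px")
  xb <- seq(0, W, length.out = nc + 1)
  yb <- seq(0, H, length.out = nr + 1)
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    k <- k + 1L
    x0 <- xb[cc] + inset * (xb[cc + 1] - xb[cc])
    x1 <- xb[cc + 1] - inset * (xb[cc + 1] - xb[cc])
    y0 <- yb[r] + inset * (yb[r + 1] - yb[r])
    y1 <- yb[r + 1] - inset * (yb[r + 1] - yb[r])
    rows <- (floor(y0) + 1):ceiling(y1); cols <- (floor(x0) + 1):ceiling(x1)
    out[[k]] <- data.frame(
      row = r, col = cc,
      R = mean(image$pixels[rows, cols, 1]),
      G = mean(image$pixels[rows, cols, 2]),
      B = mean(image$pixels[rows, cols, 3]))
  }
  do.call(rbind, out)
}

#' Colour-reproduction error report
#'
#' Per-patch delta E*ab and delta C*ab between measured and reference Lab
#' values, with their means and maxima.
#'
#' @param measured,reference n x 3 Lab matrices or data frames with columns
#'   `L`, `a`, `b`, one row per patch, same patch order.
#' @param patch_id optional patch identifiers.
#' @return An object of class `color_error_report`: list with `per_patch`
#'   (data frame of `patch_id`, `dE`, `dC`) and scalars `mean_dE`, `max_dE`,
#'   `mean_dC`, `max_dC`.
#' @export
color_error_report <- function(measured, reference, patch_id = NULL) {
  m <- as_lab_matrix(measured); r <- as_lab_matrix(reference)
  if (nrow(m) < 1L) stop("empty chart: need at least one patch")
  if (nrow(m) != nrow(r))
    stop("measured and reference patch counts differ (",
         nrow(m), " vs ", nrow(r), ")")
  if (is.null(patch_id)) patch_id <- sprintf("P%02d", seq_len(nrow(m)))
  dE <- delta_e_ab(m, r); dC <- delta_c_ab(m, r)
  structure(list(
    per_patch = data.frame(patch_id = as.character(patch_id),
                           dE = dE, dC = dC, stringsAsFactors = FALSE),
    mean_dE = mean(dE), max_dE = max(dE),
    mean_dC = mean(dC), max_dC = max(dC)),
    class = "color_error_report")
}

#' @export
print.color_error_report <- function(x, ...) {
  cat(sprintf(paste0("<color_error_report> %d patches | dE*ab mean %.2f ",
                     "max %.2f | dC*ab mean %.2f max %.2f\n"),
              nrow(x$per_patch), x$mean_dE, x$max_dE, x$mean_dC, x$max_dC))
  invisible(x)
}

roi_check <- function(roi, d, what) {
  if (length(roi) != 4L) stop(what, " must be c(x0, y0, x1, y1)")
  roi <- as.integer(roi)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] >= d[2] || roi[4] >= d[1] ||
      roi[3] < roi[1] || roi[4] < roi[2])
    stop(what, " out of bounds for a ", d[1], " x ", d[2], " frame")
  if (roi[3] - roi[1] + 1 < 32 || roi[4] - roi[2] + 1 < 32)
    stop(what, " must be at least 32 x 32 px")
  roi
}

image_to_lab <- function(image, white = "D50") {
  d <- dim(image$pixels)
  rgb <- cbind(as.vector(image$pixels[, , 1]),
               as.vector(image$pixels[, , 2]),
               as.vector(image$pixels[, , 3]))
  srgb_to_lab(rgb, white = white)
}

#' Colour-match a source image to a reference via Lab statistics transfer
#'
#' Emulates the documented default behaviour of a "match color" adjustment:
#' a per-channel affine map in CIELAB is fitted so that the source ROI's
#' channel means and standard deviations equal the reference ROI's, then
#' applied to the whole source frame and converted back to sRGB with
#' clipping. A zero-variance source channel is shifted by mean only.
#'
#' @param source,reference [raster_image()] objects.
#' @param source_roi,reference_roi regions of interest, integer
#'   `c(x0, y0, x1, y1)` in 0-based inclusive pixel coordinates, at least
#'   32 x 32 px.
#' @param l_levels optional length-2 vector of 8-bit levels (e.g.
#'   `c(20, 240)`): after matching, L* is linearly compressed into the
#'   corresponding lightness range, emulating an output-levels clamp applied
#'   in luminosity mode.
#' @return The colour-matched source as a [raster_image()].
#' @export
match_color <- function(source, source_roi, reference, reference_roi,
                        l_levels = NULL) {
  stopifnot(inherits(source, "raster_image"),
            inherits(reference, "raster_image"))
  ds <- dim(source$pixels); dr <- dim(reference$pixels)
  source_roi <- roi_check(source_roi, ds, "source_roi")
  reference_roi <- roi_check(reference_roi, dr, "reference_roi")

  lab_src <- image_to_lab(source)
  lab_ref <- image_to_lab(reference)
  roi_idx <- function(roi, d) {
    rows <- (roi[2] + 1):(roi[4] + 1); cols <- (roi[1] + 1):(roi[3] + 1)
    as.vector(outer(rows, (cols - 1) * d[1], `+`))
  }
  src_stats <- lab_src[roi_idx(source_roi, ds), , drop = FALSE]
  ref_stats <- lab_ref[roi_idx(reference_roi, dr), , drop = FALSE]

  out <- lab_src
  for (ch in 1:3) {
    mu_s <- mean(src_stats[, ch]); sd_s <- stats::sd(src_stats[, ch])
    mu_r <- mean(ref_stats[, ch]); sd_r <- stats::sd(ref_stats[, ch])
    out[, ch] <- if (sd_s > 0) (lab_src[, ch] - mu_s) * (sd_r / sd_s) + mu_r
                 else lab_src[, ch] - mu_s + mu_r
  }
  if (!is.null(l_levels)) {
    if (length(l_levels) != 2L || l_levels[1] >= l_levels[2])
      stop("l_levels must be c(low, high) 8-bit levels with low < high")
    lo <- srgb_to_lab(rep(l_levels[1], 3))[1]
    hi <- srgb_to_lab(rep(l_levels[2], 3))[1]
    out[, 1] <- lo + pmin(100, pmax(0, out[, 1])) / 100 * (hi - lo)
  }
  rgb <- lab_to_srgb(out)
  px <- array(0L, ds)
  px[, , 1] <- rgb[, 1]; px[, , 2] <- rgb[, 2]; px[, , 3] <- rgb[, 3]
  raster_image(px, mm_per_px = source$mm_per_px)
}

#' Bundled synthetic chart reference values
#'
#' A 30-patch (6 x 5) list of plausible CIELAB reference values spanning
#' skin tones, primaries and a neutral ramp. These are synthetic and NOT the
#' certified values of any commercial chart (those are vendor-proprietary);
#' supply your chart's certified CSV for real measurements.
#'
#' @return Data frame with columns `patch_id`, `L`, `a`, `b`.
#' @export
default_chart_reference <- function() {
  path <- system.file("extdata", "colorchart_synthetic_lab.csv",
                      package = "colpoqc", mustWork = TRUE)
  read_chart_reference(path)
}

#' Read a chart-reference Lab CSV
#'
#' Format: `patch_id,L,a,b` with a header line; `#` comments permitted.
#'
#' @param path path to the CSV.
#' @return Data frame with columns `patch_id`, `L`, `a`, `b`.
#' @export
read_chart_reference <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patch_id", "L", "a", "b")
  if (!all(need %in% names(df)))
    stop("chart reference CSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$L < 0 | df$L > 100)) stop("L values must lie in [0, 100]")
  if (any(abs(df$a) > 128) || any(abs(df$b) > 128))
    stop("|a| and |b| must be <= 128")
  if (anyDuplicated(df$patch_id)) stop("patch_id values must be unique")
  df[, need]
}
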