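# Spectral shape (central wavelength +/- FWHM) and beam-uniformity FWHM
# diameter from diffuser images.

#' Peak wavelength and FWHM of an emission spectrum
#'
#' The spectrum is smoothed with a 5-sample moving average (suppresses
#' spectrometer shot noise without biasing a 30-nm band by more than ~1 nm);
#' the central wavelength is the argmax, and the FWHM the distance between
#' the outermost half-maximum crossings found by linear interpolation on the
#' smoothed curve. Invariant to positive scaling of the intensities.
#'
#' @param s an [emission_spectrum()].
#' @return An object of class `spectral_shape`: list with `central_nm`,
#'   `fwhm_nm` and logical `multimodal` (TRUE when the half-max region is
#'   disjoint; the outermost crossings are still reported).
#' @export
spectrum_peak_fwhm <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  wl <- s$wavelength_nm
  it <- stats::filter(s$intensity, rep(1 / 5, 5), sides = 2)
  it <- as.numeric(it)
  # moving average is NA at the two ends; fall back to raw values there
  na <- is.na(it)
  it[na] <- s$intensity[na]
  pk <- max(it)
  if (pk <= 0) stop("spectrum has no positive intensity")
  at_max <- which(it >= pk * (1 - 1e-9))
  plateau <- max(wl[at_max]) - min(wl[at_max])
  # a flat-topped band is a legitimate peak (its centre is reported); only a
  # plateau spanning most of the grid, or a maximum pinned to an endpoint
  # (monotone ramp), leaves the central wavelength undefined
  if (plateau > 0.5 * (max(wl) - min(wl)))
    stop("ambiguous peak: maximum plateau spans most of the spectrum")
  i_pk <- at_max[ceiling(length(at_max) / 2)]
  if (min(at_max) == 1L || max(at_max) == length(wl))
    stop("ambiguous peak: maximum at the spectral grid endpoint")
  central <- wl[i_pk]

  half <- pk / 2
  above <- it >= half
  cross_up <- which(!above[-length(above)] & above[-1])      # rising
  cross_dn <- which(above[-length(above)] & !above[-1])      # falling
  interp <- function(i) {
    # linear interpolation of the half-max crossing between samples i, i+1
    wl[i] + (half - it[i]) / (it[i + 1] - it[i]) * (wl[i + 1] - wl[i])
  }
  lo <- if (length(cross_up) == 0) wl[1] else interp(min(cross_up))
  hi <- if (length(cross_dn) == 0) wl[length(wl)] else interp(max(cross_dn))
  # count disjoint half-max runs for the multimodality flag
  runs <- rle(above)
  nruns <- sum(runs$values)
  structure(list(central_nm = central, fwhm_nm = hi - lo,
                 multimodal = nruns > 1),
            class = "spectral_shape")
}

#' @export
print.spectral_shape <- function(x, ...) {
  cat(sprintf("<spectral_shape> %g +/- %.1f nm (central +/- FWHM)%s\n",
              x$central_nm, x$fwhm_nm,
              if (x$multimodal) " [multimodal]" else ""))
  invisible(x)
}

#' FWHM beam diameter from a normalized luminance map
#'
#' The half-maximum region is the set of pixels with normalized luminance
#' >= 0.5; its equivalent-area circular diameter,
#' 2 sqrt(area / pi) * mm_per_px, is reported as the FWHM beam diameter
#' (rotation-invariant; exact for a circular beam). Contour levels
#' 0.1, ..., 0.9 are included for map rendering.
#'
#' @param map a [luminance_map()] with `mm_per_px` set.
#' @return An object of class `beam_report`: list with `fwhm_diameter_mm`,
#'   `area_px` and `contour_levels`.
#' @export
beam_fwhm_diameter <- function(map) {
  stopifnot(inherits(map, "luminance_map"))
  if (is.null(map$mm_per_px))
    stop("mm_per_px is required; calibrate with calibrate_scale_from_grid()")
  v <- map$values
  H <- nrow(v); W <- ncol(v)
  half <- v >= 0.5
  if (!any(half)) stop("no pixels at or above half maximum")
  if (any(half[1, ]) || any(half[H, ]) || any(half[, 1]) || any(half[, W]))
    stop("half-max region touches the frame border: beam larger than frame")
  area <- sum(half)
  structure(list(
    fwhm_diameter_mm = 2 * sqrt(area / pi) * map$mm_per_px,
    area_px = area,
    contour_levels = seq(0.1, 0.9, 0.1)),
    class = "beam_report")
}

#' @export
print.beam_report <- function(x, ...) {
  cat(sprintf("<beam_report> FWHM diameter %.2f mm (%d px at >= 0.5)\n",
              x$fwhm_diameter_mm, x$area_px))
  invisible(x)
}

# detect periodic dark grid lines in a 1-D projection profile; returns
# sub-pixel line positions (0-based)
profile_line_positions <- function(profile) {
  n <- length(profile)
  k <- min(2L * (n %/% 20) + 1L, 31L)
  if (k < 3L) k <- 3L
  resid <- profile - stats::runmed(profile, k)
  depth <- -min(resid)
  if (depth <= 0) return(numeric(0))
  dark <- resid < -0.5 * depth
  # cluster consecutive dark indices, one line per run
  runs <- rle(dark)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pos <- numeric(0)
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    j <- idx[which.min(resid[idx])]
    if (j > 1 && j < n) {
      # parabolic sub-pixel interpolation around the dip minimum
      y1 <- resid[j - 1]; y2 <- resid[j]; y3 <- resid[j + 1]
      den <- y1 - 2 * y2 + y3
      off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      pos <- c(pos, j - 1 + max(-1, min(1, off)))
    } else {
      pos <- c(pos, j - 1)
    }
  }
  pos
}

#' Calibrate physical scale from a grid-overlay image
#'
#' The two-image beam protocol: one diffuser-only frame for the beam shape
#' and one with a reference grid (e.g. centimetre pitch) overlaid for scale.
#' Dark grid lines are detected as dips in the row and column projection
#' profiles; the scale is `pitch_mm` divided by the median line spacing.
#'
#' @param image a [raster_image()] showing the grid overlay.
#' @param pitch_mm physical grid pitch in mm.
#' @return mm per pixel (numeric scalar).
#' @export
calibrate_scale_from_grid <- function(image, pitch_mm) {
  stopifnot(inherits(image, "raster_image"))
  if (pitch_mm <= 0) stop("pitch_mm must be positive")
  y <- luma8(image)
  px <- profile_line_positions(colMeans(y))
  py <- profile_line_positions(rowMeans(y))
  if (length(px) < 3 || length(py) < 3)
    stop("calibration error: need at least 3 grid lines in each direction, ",
         "found ", length(px), " (x) and ", length(py), " (y)")
  spacing <- stats::median(c(diff(px), diff(py)))
  pitch_mm / spacing
}
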