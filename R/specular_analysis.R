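# Hot-pixel specular-reflection fraction and the maximum illumination power
# satisfying a specular threshold.

#' Specular-reflection ("hot pixel") fraction of an image
#'
#' Percentage of pixels whose un-normalized Rec.601 luma on the 8-bit scale
#' is strictly greater than the threshold (default 250, the conventional
#' hot-pixel cut; the boundary value itself does not count).
#'
#' @param image a [raster_image()].
#' @param luma_threshold hot-pixel luma cut on the 0-255 scale.
#' @return Percentage in \[0, 100\].
#' @export
specular_fraction <- function(image, luma_threshold = 250) {
  stopifnot(inherits(image, "raster_image"))
  y <- luma8(image)
  100 * sum(y > luma_threshold) / length(y)
}

#' Specular sweep: specular fraction vs optical power
#'
#' @param power_mW strictly increasing optical powers, mW (or any monotone
#'   drive-level axis).
#' @param fraction_percent specular fractions in \[0, 100\], same length.
#' @param threshold_percent acceptance bound used by [power_limit()].
#'   Field presets: 1.0 (legacy), 0.5 (white light), 0.05 (green light).
#' @return An object of class `specular_sweep`.
#' @export
specular_sweep <- function(power_mW, fraction_percent,
                           threshold_percent = 0.5) {
  if (length(power_mW) < 2L) stop("a sweep needs at least 2 points")
  if (length(fraction_percent) != length(power_mW))
    stop("power and fraction lengths differ")
  if (any(power_mW < 0) || any(diff(power_mW) <= 0))
    stop("powers must be non-negative and strictly increasing")
  if (any(fraction_percent < 0 | fraction_percent > 100))
    stop("fractions must lie in [0, 100]")
  if (threshold_percent <= 0) stop("threshold_percent must be positive")
  structure(list(power_mW = as.numeric(power_mW),
                 fraction_percent = as.numeric(fraction_percent),
                 threshold_percent = threshold_percent),
            class = "specular_sweep")
}

#' @export
print.specular_sweep <- function(x, ...) {
  cat(sprintf("<specular_sweep> %d points, %.3g-%.3g mW, threshold %.3g%%\n",
              length(x$power_mW), min(x$power_mW), max(x$power_mW),
              x$threshold_percent))
  invisible(x)
}

#' Maximum permissible optical power from a specular sweep
#'
#' The largest power whose specular fraction stays at or below the sweep's
#' threshold. When the threshold falls between two sampled powers, the
#' crossing is located by linear interpolation between the bracketing points
#' (measured limits are customarily reported at finer precision than the
#' sweep grid). If every point passes, the largest sampled power is returned
#' with `at_boundary = TRUE`.
#'
#' @param sweep a [specular_sweep()]. Fractions must be non-decreasing in
#'   power; violations up to 0.02 percentage points are tolerated as
#'   measurement noise.
#' @return Power limit in mW, with attribute `at_boundary`.
#' @export
power_limit <- function(sweep) {
  stopifnot(inherits(sweep, "specular_sweep"))
  p <- sweep$power_mW; f <- sweep$fraction_percent
  thr <- sweep$threshold_percent
  dec <- -diff(f)
  if (any(dec > 0.02))
    stop("data-quality error: specular fraction decreases by ",
         format(max(dec), digits = 3), " percentage points with rising power")
  if (all(f > thr))
    stop("no safe power: every sampled point exceeds the ", thr,
         "% specular threshold")
  if (all(f <= thr)) {
    out <- p[length(p)]
    attr(out, "at_boundary") <- TRUE
    return(out)
  }
  i <- max(which(f <= thr))             # last passing point
  # first failing point after i (monotone up to tolerance, so i + 1 fails)
  j <- i + 1L
  out <- if (f[j] == f[i]) p[i] else
    p[i] + (thr - f[i]) / (f[j] - f[i]) * (p[j] - p[i])
  attr(out, "at_boundary") <- FALSE
  out
}

#' Simulated specular sweep over a synthetic cervix scene
#'
#' Renders one synthetic cervix scene and re-exposes it at each gain
#' (pixel intensities scaled and clipped to 255), recording the specular
#' fraction per step: a software stand-in for stepping the source's optical
#' power. Clipping makes the fraction non-decreasing in gain by
#' construction.
#'
#' @param spec a [scene_spec()] for the underlying scene.
#' @param gains strictly increasing non-negative power multipliers; the
#'   sweep's power axis is `gains * base_power_mW`.
#' @param base_power_mW nominal optical power at gain 1, mW.
#' @param threshold_percent specular threshold carried into the sweep.
#' @param green_mode render the scene under the green-field palette.
#' @return A [specular_sweep()].
#' @export
run_sweep <- function(spec, gains, base_power_mW = 1,
                      threshold_percent = 0.5, green_mode = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (any(gains < 0) || any(diff(gains) <= 0))
    stop("gains must be non-negative and strictly increasing")
  base <- gen_cervix_scene(spec, specular_fraction = 0,
                           green_mode = green_mode)
  fr <- vapply(gains, function(g) {
    px <- pmin(255, round(base$pixels * g))
    specular_fraction(raster_image(array(px, dim(base$pixels))))
  }, numeric(1))
  specular_sweep(gains * base_power_mW, fr,
                 threshold_percent = threshold_percent)
}
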