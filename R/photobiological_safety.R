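# Lamp-safety maximum-permissible-emission assessment in the style of
# ANSI/IESNA recommended practice: spectrally weighted radiances L_B
# (blue-light hazard, B(lambda), 300-700 nm) and L_R (retinal thermal hazard,
# R(lambda), 400-1400 nm), angular subtense with clamping, and exempt-group
# classification. Both weighted quantities are treated as radiances
# (W cm^-2 sr^-1), consistent with the per-steradian exempt limits.

#' Load a hazard weighting function
#'
#' Bundled 5-nm node tables of the standard published lamp-safety weightings:
#' `"B"` for blue-light hazard (300-700 nm, maximum 1.0 in the 435-440 nm
#' region) and `"R"` for retinal thermal (burn) hazard (400-1400 nm). Linear
#' interpolation between nodes, zero outside the tabulated range.
#'
#' @param which `"B"` or `"R"`, or a path to a `wavelength_nm,weight` CSV.
#' @return An object of class `hazard_weighting`: list with `wavelength_nm`,
#'   `weight`, `range_nm` and interpolator `w(lambda)`.
#' @export
hazard_weighting <- function(which = c("B", "R")) {
  path <- if (which %in% c("B", "R")) {
    system.file("extdata",
                if (which == "B") "blue_light_hazard_B.csv"
                else "retinal_thermal_hazard_R.csv",
                package = "colpoqc", mustWork = TRUE)
  } else {
    if (!file.exists(which) || dir.exists(which))
      stop("weighting table not found: ", which)
    which
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "weight") %in% names(df)))
    stop("weighting table needs columns wavelength_nm, weight")
  if (any(df$weight < 0)) stop("weights must be non-negative")
  if (is.unsorted(df$wavelength_nm, strictly = TRUE))
    stop("weighting wavelengths must be strictly increasing")
  if (identical(which, "B")) {
    pk <- df$wavelength_nm[df$weight >= max(df$weight) - 1e-12]
    if (max(df$weight) != 1 || min(pk) < 435 || max(pk) > 440)
      stop("blue-light table must peak at 1.0 within 435-440 nm")
  }
  wfun <- stats::approxfun(df$wavelength_nm, df$weight, rule = 1)
  structure(list(
    wavelength_nm = df$wavelength_nm, weight = df$weight,
    range_nm = range(df$wavelength_nm),
    w = function(lambda) {
      out <- wfun(lambda)
      out[is.na(out)] <- 0
      out
    }),
    class = "hazard_weighting")
}

#' Angular subtense of a source, with regulatory clamping
#'
#' alpha = L / R with L the 50%-peak beam extent and R the working distance;
#' the guidelines clamp alpha to \[0.011, 0.11\] radians before computing
#' limits.
#'
#' @param L_mm beam diameter (50% peak extent), mm.
#' @param R_mm working distance, mm.
#' @return An object of class `source_geometry`: list with
#'   `beam_diameter_mm`, `working_distance_mm`, `alpha_raw` and the clamped
#'   `alpha_rad`.
#' @export
angular_subtense <- function(L_mm, R_mm) {
  if (L_mm <= 0 || R_mm <= 0) stop("L_mm and R_mm must be positive")
  raw <- L_mm / R_mm
  structure(list(beam_diameter_mm = L_mm, working_distance_mm = R_mm,
                 alpha_raw = raw,
                 alpha_rad = min(0.11, max(0.011, raw))),
            class = "source_geometry")
}

#' Spectrally weighted radiance
#'
#' Rectangle-rule sum sum(L_lambda * w(lambda) * delta_lambda) over the
#' weighting's support, matching the guideline formula. The spectrum must be
#' in absolute units (W cm^-2 nm^-1 sr^-1), or an explicit `scale` factor
#' converting its relative intensities to absolute spectral radiance must be
#' given: the package never guesses radiometric calibration.
#'
#' @param s an [emission_spectrum()].
#' @param w a [hazard_weighting()].
#' @param scale optional multiplicative absolute-calibration factor for
#'   relative-units spectra.
#' @return Weighted radiance in W cm^-2 sr^-1.
#' @export
weighted_radiance <- function(s, w, scale = NULL) {
  stopifnot(inherits(s, "emission_spectrum"),
            inherits(w, "hazard_weighting"))
  if (s$units != "absolute" && is.null(scale))
    stop("spectrum is in relative units: provide absolute calibration via ",
         "'scale' (W cm^-2 nm^-1 sr^-1 per count) or an absolute spectrum")
  if (is.null(scale)) scale <- 1
  sum(s$intensity * scale * w$w(s$wavelength_nm)) * s$delta_lambda_nm
}

#' Photobiological hazard assessment of a source
#'
#' Computes the blue-light and retinal-thermal weighted radiances, compares
#' them with the exempt-group limits (10 W cm^-2 sr^-1 for L_B over a
#' 10,000 s exposure; 2.8 / alpha W cm^-2 sr^-1 for L_R over 10 s, alpha
#' clamped to \[0.011, 0.11\] rad), and returns per-hazard verdicts. L_B is
#' also reported in mW cm^-2 sr^-1, the customary display unit.
#'
#' @param s an [emission_spectrum()] in absolute units (or with `scale`).
#' @param geom a [source_geometry()] from [angular_subtense()].
#' @param scale optional absolute-calibration factor (see
#'   [weighted_radiance()]).
#' @return An object of class `hazard_assessment`.
#' @export
assess_hazard <- function(s, geom, scale = NULL) {
  stopifnot(inherits(geom, "source_geometry"))
  wB <- hazard_weighting("B"); wR <- hazard_weighting("R")
  L_B <- weighted_radiance(s, wB, scale = scale)
  L_R <- weighted_radiance(s, wR, scale = scale)
  limit_B <- 10
  limit_R <- 2.8 / geom$alpha_rad
  structure(list(
    L_B = L_B, L_B_mW = 1000 * L_B, L_R = L_R,
    limit_B = limit_B, limit_R = limit_R,
    exempt_B = L_B <= limit_B, exempt_R = L_R <= limit_R,
    exempt = L_B <= limit_B && L_R <= limit_R,
    geometry = geom),
    class = "hazard_assessment")
}

#' @export
print.hazard_assessment <- function(x, ...) {
  cat(sprintf(
    paste0("<hazard_assessment> L_B %.3g mW/cm^2/sr (limit %.3g W: %s) | ",
           "L_R %.3g W/cm^2/sr (limit %.4g: %s) | alpha %.3g rad\n"),
    x$L_B_mW, x$limit_B, if (x$exempt_B) "exempt" else "NON-EXEMPT",
    x$L_R, x$limit_R, if (x$exempt_R) "exempt" else "NON-EXEMPT",
    x$geometry$alpha_rad))
  invisible(x)
}
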