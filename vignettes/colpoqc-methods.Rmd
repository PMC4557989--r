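---
title: "Methods: device characterization metrics in colpoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device characterization metrics in colpoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colpoqc)
```

`colpoqc` packages the bench battery used to compare digital colposcopes:
geometric image quality, colour reproduction, illumination shape, lamp
safety, and specular glare. This vignette documents the models behind each
metric, the parameters that matter, what the synthetic generators do and do
not emulate, and the numerical choices a maintainer would want written down.

## Conventions

Pixels are 8-bit RGB throughout; deeper sources are down-converted at read
time, because the consumer-grade devices this battery targets deliver 8-bit
JPEG and no raw access. Pixel coordinates are 0-based, row-major, origin at
the top-left pixel centre; physical scale is a single isotropic `mm_per_px`.
"Luminance" always means Rec.601 luma, Y = 0.299 R + 0.587 G + 0.114 B,
computed on the 8-bit values. The field's "luminous channel" for hot-pixel
counting is not standardized; we adopt this luma (rather than a single
channel) because it matches common imaging practice and keeps the
conventional 0–255 threshold scale meaningful. Normalized luminance maps
divide by the frame maximum, so an all-black frame maps to zeros rather
than NaN.

## Geometry

**Resolution.** The USAF-1951 chart is pure arithmetic: frequency
2^(group + (element−1)/6) lp/mm, bar width 500/f µm (half the line-pair
period — this is the definition that reproduces the customary printed
values, e.g. 22.1 µm for group 4 element 4). A bench protocol decides
"resolvable" with human observers; observers cannot be packaged, so the
objective stand-in is a Michelson-contrast probe
(`michelson_contrast()` ≥ 10 % over the bar region).

**Distortion.** The SMIA TV convention on a detected corner grid: A₁ and A₂
are the vertical extents of the leftmost and rightmost corner columns, B the
central column's, and distortion = 100·(A−B)/B with A = (A₁+A₂)/2. Negative
values are barrel. The printed formula in bench reports is frequently
garbled; the SMIA 1.0 reading above is the one consistent with the named
standard and with "undistorted squares have 0 %". A ±0.05 percentage-point
deadband separates `none` from a labelled direction; it is the detection
noise floor measured on undistorted synthetic fixtures (the pipeline's
residual there is ~10⁻¹⁴ %, so the deadband is generous).

**Corner detection.** Checkerboard corners are saddle points of the
intensity surface. `detect_grid()` smooths the luma (Gaussian, σ = 2 px),
takes the Hessian saddle response Ixy² − Ixx·Iyy, non-maximum-suppresses,
and assembles the lattice by walking right/down neighbour links (accepted
only within [0.6, 1.45] of the estimated pitch with bounded shear, so
lattice holes never alias into wrong indices; this survives the row
curvature a radial warp introduces, where naive 1-D coordinate clustering
fails). Sub-pixel positions come from an iterated gradient-orthogonality
solve — the corner q minimizing Σ w(p)·(∇I(p)·(p−q))² over a window scaled
to ~0.35 of the pitch. On rendered targets this lands within ~0.2 px of
ground truth; the grid needs squares of roughly 8 px or more, and the
strongest warps (|k1| near 0.2) need ~20 px squares for the same headroom.

**Field of view.** `square_mm` divided by the median corner spacing gives
mm/px; times the frame diagonal gives the diagonal field of view. Row/column
spacing disagreement above 5 % raises a calibration warning and the mean is
used. Magnification for fixed-lens digital systems has no unique optical
definition, so `magnification()` is the ratio of a declared reference field
to the measured one — a choice, stated once.

## Colour

The conversion chain is the standard one: sRGB gamma expansion, the IEC
61966-2-1 matrix to XYZ (D65 primaries), Bradford adaptation to the working
white, CIELAB. Chart work defaults to **D50** because calibrated reflective
targets are specified and imaged under D50/5000 K illumination. ΔE\*ab is
the Euclidean Lab distance; ΔC\*ab drops the L axis. The package's own
implementation is tested against `grDevices::convertColor` as an independent
oracle (agreement < 0.5 ΔE at D65 on random 8-bit triples; the small residual
is convertColor's different adaptation details).

`extract_patches()` samples each chart cell's central region after insetting
25 % per side — enough to stay clear of printed patch borders while keeping
~n/4 of the pixels for averaging. The bundled reference list
(`default_chart_reference()`) is **synthetic and non-certified**: real chart
values are vendor-proprietary, so a plausible in-gamut 30-patch D50 set is
shipped for self-contained runs and certified CSVs are supplied by the user
via `read_chart_reference()`.

`match_color()` emulates the documented default behaviour of a desktop
"match color" adjustment as per-channel affine statistics transfer in Lab:
the source ROI's channel means and standard deviations are mapped onto the
reference ROI's, the fitted transform applied to the whole frame, and the
result clipped back to sRGB. A zero-variance channel is shifted by mean
only. The optional `l_levels` argument compresses L into the lightness range
of a given 8-bit level pair, mirroring an output-levels clamp applied in
luminosity mode. This cancels any affine Lab cast exactly up to gamut
clipping and 8-bit quantization, which is precisely the property the tests
assert; it does not reproduce proprietary tool internals beyond that
documented behaviour.

## Illumination

`spectrum_peak_fwhm()` smooths with a fixed 5-sample moving average
(suppresses spectrometer shot noise; biases a 30 nm band by well under
1 nm), reports the argmax as the central wavelength, and finds the outermost
half-maximum crossings by linear interpolation. Two deliberate semantics: a
flat-topped band (e.g. a rectangular 500–560 nm pass-band) is a legitimate
peak whose centre is the plateau midpoint — only a maximum pinned to a grid
endpoint (monotone ramp) or a plateau spanning more than half the sampled
range is an ambiguous-peak error; and disjoint half-max regions are reported
with the outermost crossings plus a `multimodal` flag rather than an error,
since two-peak white-LED spectra are the normal case.

`beam_fwhm_diameter()` takes the ≥ 0.5 normalized-luminance region and
reports its equivalent-area circular diameter, 2·√(area/π)·mm_per_px. Among
the candidate readings of "FWHM beam diameter" (single horizontal cut,
bounding circle, equivalent area) the equivalent-area diameter is
rotation-invariant and exact for a circular beam, and the beams this battery
compares are near-circular; for an elliptical beam it returns √(fx·fy). A
half-max region touching the frame border is an error (beam larger than
frame), not a number. The two-image bench protocol maps to two calls:
`calibrate_scale_from_grid()` on the grid-overlay frame (projection-profile
dips, median line spacing), then `beam_fwhm_diameter()` on the beam-only
frame.

## Photobiological safety

The blue-light and retinal-thermal weighted radiances are rectangle-rule
sums L = Σ L_λ·w(λ)·Δλ over the weighting supports (300–700 nm for B(λ),
400–1400 nm for R(λ)), matching the printed Σ·Δλ formula; tests bound the
difference from an independent trapezoid quadrature below 1 %. The weighting
tables are bundled at 5 nm nodes from the standard published lamp-safety
functions with linear interpolation and zero outside support; B(λ) peaks at
1.0 in 435–440 nm, which is asserted at load time. Exempt limits are
10 W·cm⁻²·sr⁻¹ for L_B (10,000 s basis) and 2.8/α W·cm⁻²·sr⁻¹ for L_R
(10 s basis), with α = beam diameter / working distance clamped to
[0.011, 0.11] rad — hence the familiar 25.45 W·cm⁻²·sr⁻¹ ceiling once a
source subtends more than 0.11 rad. Both weighted quantities are treated as
radiances; bench write-ups sometimes label L_R an irradiance, but the
per-steradian limits fix the units. Spectra must be in absolute units
(W·cm⁻²·nm⁻¹·sr⁻¹) or accompanied by an explicit `scale` factor: the
package never guesses radiometric calibration, because the absolute chain
(power meter, attenuators, geometry) is not reproducible in software.

## Specular analysis

`specular_fraction()` is the percentage of pixels with luma **strictly**
greater than 250 (the boundary value does not count). `power_limit()`
returns the largest swept power whose fraction stays at or below the
threshold, linearly interpolating when the crossing falls between samples —
measured limits are customarily reported finer than an 11-step sweep grid,
which implies interpolation. Threshold presets follow field practice: 1 %
(legacy), 0.5 % for white light, 0.05 % for green. Fractions must be
non-decreasing in power; dips beyond 0.02 percentage points are a
data-quality error rather than silently reordered data. `run_sweep()` is the
software stand-in for the physical sweep: one rendered scene re-exposed at
each gain with clipping at 255, which makes monotonicity structural. The
published per-device limits (fractions of a mW) depend on the physical
scene and optics and are therefore out of reach of any simulation; the sweep
logic is validated by construction and hand-computed oracles instead.

## Synthetic targets: the stated world

Every generator is a pure function of (scene spec, parameters, seed): no
global RNG state is consumed or left behind, so outputs are byte-identical
across calls and platforms.

* **Checkerboard** (`gen_checkerboard`): 2 mm squares by default — the
  bench-standard target. The warp is the single-coefficient Brown model,
  r′ = r(1 + k1·r²) with r normalized to the half-diagonal; it is the
  simplest model producing controllable barrel/pincushion of either sign,
  and |k1| ≤ 0.2 spans the distortion range (≈0.5–5 %) reported for real
  devices. Rendering pulls each output pixel back through the numerically
  inverted warp and supersamples 5×5 for antialiasing (at 3×3 the 10-level
  edge quantization leaves ~0.3 px of systematic corner bias; 5×5 halves
  it). True warped corner positions ride along as ground truth.
* **Bar target** (`gen_usaf_bars`): the 3+3 bar pattern at the analytic
  width with exact coverage antialiasing. No optical blur is simulated, so
  rendered bars are always high-contrast; resolvability testing blurs
  explicitly.
* **Colour chart** (`gen_color_chart`): 24 or 30 patches filled with the
  sRGB rendering of reference Lab values, an optional 3×3 linear-RGB cast,
  and seeded Gaussian noise (`noise_sd` on the 8-bit scale; 2 is a realistic
  consumer-sensor patch noise). The cast models channel gain errors only —
  no spatially varying illumination, no chroma-dependent sensor response.
* **Beams** (`gen_beam`): radially symmetric Gaussian (σ = FWHM/2.3548) or
  flat-top disc with a 1 px soft edge, optional dark grid overlay for scale
  calibration. Real beams' mild asymmetry and speckle are not modelled.
* **Spectra** (`gen_spectrum`): white LED as blue 450 nm die + broad
  phosphor band near 550 nm (two Gaussians), halogen as a Planck curve
  normalized to unit peak (3200 K default, a typical filament temperature),
  filters as ideal 0/1 transmissions with a 5 nm linear roll-off. These
  reproduce the qualitative shapes of real sources without copying any
  measured trace.
* **Cervix scene** (`gen_cervix_scene`): a pink ellipse with darker os and
  random-walk vessels on a dark background, green-field palette optional.
  Base colours are chosen so no non-specular pixel can exceed luma 250,
  and exactly `round(fraction/100 · H·W)` pixels are saturated — the scene
  matches the *statistical* property the specular metric needs and nothing
  more. It is not photorealistic and says nothing about real polarization
  or tissue optics.

A green test on these fixtures establishes that the metric implementations
are correct against analytic ground truth; it does not certify any physical
device, and it cannot validate absolute radiometric calibration, optical
PSFs, or sensor nonlinearity, none of which the generators emulate.

## Numerical choices and degenerate inputs

* Warp inversion: 40 damped fixed-point iterations of
  ρ ← ρ′/(1 + k1·ρ²); converges to machine precision for |k1| ≤ 0.5,
  ρ ≤ 1.
* Corner refinement window: 0.35× the estimated pitch, clamped to
  [3, 10] px; six iterations or convergence at 10⁻⁵ px².
* `pmin/pmax` with scalar first arguments drop `dim` in R; all clamping of
  image arrays goes through a dims-preserving helper.
* Duplicate spectrum wavelengths are averaged; the bin width Δλ defaults to
  the median spacing, and an explicit `delta_lambda_nm` overrides it for
  non-uniform grids.
* An all-black frame yields a zero luminance map (not NaN); a beam with no
  ≥ half-max pixels, or one touching the border, errors rather than
  reporting a truncated diameter.
* Distortion ties at the ±0.05 % deadband boundary are labelled by strict
  inequality (exactly ±0.05 is `none`).
* The specular threshold is strict (`> 250`); a frame of luma-250 pixels
  has fraction 0.
* 16-bit image sources are down-converted by integer division (value ÷ 256)
  at read time; this path exists for PNG but cannot be exercised in the
  offline test environment (no available writer emits 16-bit files).

## Known limitations

* TIFF support is a minimal in-package codec: uncompressed baseline 8-bit
  gray/RGB only (no compression schemes, tiles, or exotic layouts); it
  exists because no TIFF package is available in the target environment.
* `detect_grid()` assumes an axis-aligned grid (no in-plane rotation beyond
  the shear the warp itself induces) and a single checkerboard filling the
  frame.
* The hazard module implements only the exempt-group test for the two
  hazards this battery uses; the full risk-group ladder and other weightings
  (actinic UV, IR cornea/lens) are out of scope.
* `match_color()` matches first and second moments per Lab channel; it will
  not linearize a strongly non-affine colour distortion.
* The comparison report (`characterize()`) performs no arithmetic of its
  own: every number in it is the untouched output of one metric call, with
  provenance (input paths) recorded per device.
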