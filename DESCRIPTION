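Package: colpoqc
Title: Image Quality, Illumination and Photobiological Safety Metrics for
    Digital Colposcopes
Version: 0.1.0
Authors@R:
    person("QC", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A characterization battery for low-cost digital colposcopes and
    similar point-of-care imaging devices. Computes resolving power from
    USAF-1951 bar-target geometry, diagonal field of view and SMIA TV radial
    lens distortion from checkerboard images, CIELAB colour-reproduction
    error (delta E*ab, delta C*ab) against a calibrated chart, emission
    spectrum peak and full width at half maximum, beam-uniformity FWHM
    diameter from diffuser images, lamp-safety weighted radiances (blue-light
    and retinal-thermal hazard) with exempt-group classification, and the
    specular-reflection ("hot pixel") fraction of clinical scenes. Ships
    deterministic, seeded generators for every input class (warped
    checkerboards, bar targets, colour charts, beam profiles, LED/halogen
    spectra, cervix-like scenes) so the full pipeline is testable without
    physical captures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
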