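Package: cbctdi
Title: Cone-Beam CT Dose Index and Dose-Length Product Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dosimetry toolkit for kilovoltage cone-beam CT (CBCT). Generates
    synthetic axial dose profiles with a rect-convolved scatter line-spread
    function (flat primary core of the actual collimation width plus long
    exponential scatter tails), computes dose-profile integrals (DPI), the
    aperture-normalized cone-beam CTDI, weighted CTDI with Bakalyar 1/2-1/2
    coefficients, mean weighted CTDI, dose-length product (DLP), truncated
    pencil-chamber indices (CTDI100, D100bar, CTDI300) and central ray dose
    f(0), and supports radiochromic-film densitometry: ROI statistics, net
    optical density, monotone pixel-value-to-exposure calibration, and
    normalized axial profile extraction with FWHM beam-width measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
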