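# A plausible radiochromic response for synthesis: NOD linear in exposure,
# so pv = pv0 * 10^(-k * E). Used to build calibration points and render
# synthetic strips; independent of the package's interpolation.
film_response_pv <- function(exposure_R, pv0 = 40000, k = 0.25) {
  pv0 * 10^(-k * exposure_R)
}

make_curve <- function(max_R = 2, n = 12, ...) {
  E <- seq(0, max_R, length.out = n)
  build_calibration(data.frame(pixel_value = film_response_pv(E, ...),
                               exposure_R = E))
}

test_that("ROI mean of the red channel is an arithmetic mean", {
  img <- array(30000, dim = c(20, 30, 3))
  strip <- film_strip(img)
  expect_equal(roi_mean_red(strip, c(1, 20, 1, 30)), 30000)

  # checkerboard of 0/65535 over an even pixel count
  chk <- outer(1:20, 1:30, function(i, j) ((i + j) %% 2) * 65535)
  img2 <- array(rep(chk, 3), dim = c(20, 30, 3))
  expect_equal(roi_mean_red(film_strip(img2), c(1, 20, 1, 30)), 65535 / 2)

  # ~500-pixel ROI against a brute-force sum
  set.seed(3)
  vals <- matrix(runif(50 * 60, 1000, 60000), 50, 60)
  img3 <- array(rep(vals, 3), dim = c(50, 60, 3))
  roi <- c(11, 30, 16, 40)  # 20 x 25 = 500 px
  expect_equal(roi_mean_red(film_strip(img3), roi),
               sum(vals[11:30, 16:40]) / 500)

  expect_error(roi_mean_red(strip, c(0, 5, 1, 5)), "bounds")
  expect_error(roi_mean_red(strip, c(5, 1, 1, 5)), "bounds")
})

test_that("net optical density follows the reflective log ratio", {
  expect_equal(net_optical_density(40000, 40000), 0)
  expect_equal(net_optical_density(4000, 40000), 1)
  expect_equal(net_optical_density(20000, 40000), log10(2))
  expect_error(net_optical_density(41000, 40000), "negative NOD")
  expect_error(net_optical_density(0, 40000), "> 0")
})

test_that("calibration interpolates through every point and refuses extrapolation", {
  crv <- make_curve()
  pts <- crv$points
  expect_equal(pv_to_exposure(crv, pts$pixel_value), pts$exposure_R,
               tolerance = 1e-9)
  # unexposed knot maps to 0 R
  expect_equal(pv_to_exposure(crv, 40000), 0)

  # cubic reproduces linear data between knots
  lin <- build_calibration(data.frame(pixel_value = c(40000, 30000, 20000, 10000),
                                      exposure_R = c(0, 1, 2, 3)))
  expect_equal(pv_to_exposure(lin, 25000), 1.5, tolerance = 1e-9)

  # withheld midpoints of a smooth response recovered within 2%
  E_dense <- seq(0.1, 1.9, 0.2)
  rec <- pv_to_exposure(crv, film_response_pv(E_dense))
  expect_lt(max(abs(rec - E_dense) / E_dense), 0.02)

  expect_error(pv_to_exposure(crv, 70000), "extrapolation refused")
  expect_error(pv_to_exposure(crv, 100), "extrapolation refused")
  expect_error(exposure_to_pv(crv, 5), "extrapolation refused")
})

test_that("calibration rejects non-monotone or degenerate point sets", {
  expect_error(build_calibration(data.frame(pixel_value = c(1, 2), exposure_R = c(0, 1))),
               "at least 3")
  expect_error(build_calibration(data.frame(pixel_value = c(40000, 42000, 20000),
                                            exposure_R = c(0, 1, 2))),
               "decrease strictly")
  expect_error(build_calibration(data.frame(pixel_value = c(40000, 30000, 30000),
                                            exposure_R = c(0, 1, 2))),
               "duplicate pixel values")
})

test_that("pv -> exposure -> dose chain is monotone nonincreasing in pv", {
  crv <- make_curve()
  set.seed(11)
  pv <- sort(runif(1000, crv$pv_range[1], crv$pv_range[2]))
  dose <- exposure_to_dose(pv_to_exposure(crv, pv))
  expect_true(all(diff(dose) <= 1e-12))
})

test_that("exposure-to-dose applies the roentgen-to-rad factor", {
  expect_equal(exposure_to_dose(1), 0.869)
  expect_equal(exposure_to_dose(0), 0)
  expect_equal(exposure_to_dose(16.07), 16.07 * 0.869)
  expect_equal(dose_to_exposure(exposure_to_dose(2.3)), 2.3)
  expect_error(exposure_to_dose(-1), ">= 0")
})

test_that("FWHM measures rectangles, blurred rectangles and triangles", {
  z <- default_z_grid(0.5, 100)
  rect <- dose_profile(z, 1 * (abs(z) < 10) + 0.5 * (abs(z) == 10))
  expect_equal(measure_beam_width_fwhm(rect), 20, tolerance = 0.5 / 20)

  blur <- generate_profile(20, scatter_params(1, 0, 5, penumbra_sigma = 1),
                           z_grid = default_z_grid(0.25, 450))
  expect_equal(measure_beam_width_fwhm(blur), 20, tolerance = 0.1 / 20)

  tri <- dose_profile(z, pmax(0, 1 - abs(z) / 20))
  expect_equal(measure_beam_width_fwhm(tri), 20, tolerance = 1e-9)

  flat <- dose_profile(z, rep(1, length(z)))
  expect_error(measure_beam_width_fwhm(flat), "half maximum")
})

test_that("film round trip recovers the normalized profile within 1%", {
  # known smooth profile (2 mm penumbra resolves the 0.353 mm pixel pitch)
  prm <- scatter_params(1, 0.4, 50, penumbra_sigma = 2)
  truth <- generate_profile(60, prm)
  crv <- make_curve(max_R = 2)

  strip <- render_film_strip(truth, crv, dpi = 72)
  expect_equal(25.4 / strip$dpi, 0.3528, tolerance = 1e-4)

  prof <- extract_normalized_profile(strip, crv)
  expect_equal(f0(prof), 1, tolerance = 1e-6)

  ref <- approx(truth$z_mm, truth$dose_cgy, prof$z_mm)$y / f0(truth)
  keep <- !is.na(ref) & ref > 0.05
  expect_lt(max(abs(prof$dose_cgy[keep] - ref[keep]) / ref[keep]), 0.01)

  # saturated pixels outside the calibrated range are reported by column
  hot <- truth
  hot$dose_cgy <- truth$dose_cgy * 3
  expect_error(extract_normalized_profile(render_film_strip(hot, make_curve(max_R = 4)), crv),
               "outside calibration")
})

test_that("film strips round-trip through 16-bit TIFF", {
  set.seed(9)
  img <- array(runif(10 * 40 * 3, 0, 65535), dim = c(10, 40, 3))
  strip <- film_strip(round(img))
  path <- file.path(withr::local_tempdir(), "strip.tif")
  write_film_tiff(strip, path)
  back <- read_film_tiff(path)
  expect_equal(back$image, strip$image, tolerance = 1e-7)

  expect_warning(film_strip(array(100, dim = c(4, 4, 3))), "8-bit")
})
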