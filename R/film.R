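# Radiochromic film densitometry: scanned strip ROI statistics, net optical
# density, monotone pixel-value -> exposure calibration, exposure -> dose
# conversion, and normalized axial profile extraction.

# exposure (R, in air) -> absorbed dose to air (rad = cGy)
.ROENTGEN_TO_RAD <- 0.869
# dose-to-air -> dose-to-film
.DOSE_TO_FILM <- 1.00

#' Film strip container
#'
#' A scanned radiochromic strip: a 2D RGB image (rows x cols x 3), the scan
#' resolution, and which image axis runs along the rotation axis z.
#' Channel values are scanner counts on a 16-bit scale (0-65535); 8-bit
#' images are accepted with a warning and rescaled.
#'
#' @param image Numeric array `rows x cols x 3`.
#' @param dpi Scan resolution in dots per inch.
#' @param z_axis `"columns"` (z runs along image columns, the default for a
#'   landscape strip) or `"rows"`.
#' @return An object of class `film_strip`.
#' @export
film_strip <- function(image, dpi = 72, z_axis = c("columns", "rows")) {
  z_axis <- match.arg(z_axis)
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop("image must be a rows x cols x 3 (RGB) array", call. = FALSE)
  }
  if (dpi <= 0) stop("dpi must be > 0", call. = FALSE)
  if (any(dim(image)[1:2] == 0)) stop("image must be nonempty", call. = FALSE)
  if (max(image) <= 255 && max(image) > 1) {
    warning("image looks 8-bit; rescaling counts to the 16-bit scale")
    image <- image * 257
  }
  structure(list(image = image, dpi = dpi, z_axis = z_axis),
            class = "film_strip")
}

#' Read a film strip from a TIFF scan
#'
#' Reads an RGB TIFF (no color management) and converts channel values to
#' 16-bit scanner counts.
#'
#' @param path TIFF file path.
#' @param dpi Scan resolution in dots per inch (scans at 72 dpi give a
#'   0.3528 mm pixel pitch).
#' @param z_axis Image axis running along z; see [film_strip()].
#' @return A `film_strip`.
#' @export
read_film_tiff <- function(path, dpi = 72, z_axis = "columns") {
  img <- tiff::readTIFF(path)  # values in [0, 1]
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  film_strip(img[, , 1:3, drop = FALSE] * 65535, dpi = dpi, z_axis = z_axis)
}

#' Write a film strip to TIFF
#'
#' @param strip A `film_strip`.
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_film_tiff <- function(strip, path) {
  stopifnot(inherits(strip, "film_strip"))
  tiff::writeTIFF(strip$image / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Mean red-channel pixel value over a rectangular ROI
#'
#' Radiochromic film is read in the red channel, where its absorption is
#' most sensitive; a ~500 pixel ROI mean is the standard representative
#' pixel value for calibration spots.
#'
#' @param strip A `film_strip`.
#' @param roi Integer vector `c(row1, row2, col1, col2)` (inclusive bounds,
#'   1-based).
#' @return Mean red-channel value (scanner counts).
#' @export
roi_mean_red <- function(strip, roi) {
  stopifnot(inherits(strip, "film_strip"), length(roi) == 4)
  d <- dim(strip$image)
  if (roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 || roi[4] > d[2] ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("ROI out of image bounds or empty", call. = FALSE)
  }
  mean(strip$image[roi[1]:roi[2], roi[3]:roi[4], 1])
}

#' Net optical density of an exposed film reading
#'
#' Reflective densitometry convention: `NOD = log10(PV_unexposed / PV)`.
#' Zero for unexposed film; increases as the film darkens.
#'
#' @param pv Pixel value of the exposed region.
#' @param pv_unexposed Pixel value of the unexposed film.
#' @return Net optical density (dimensionless).
#' @examples
#' net_optical_density(20000, 40000)  # log10(2) = 0.30103
#' @export
net_optical_density <- function(pv, pv_unexposed) {
  stopifnot(length(pv_unexposed) == 1)
  if (pv_unexposed <= 0 || any(pv <= 0)) stop("pixel values must be > 0", call. = FALSE)
  if (any(pv > pv_unexposed)) {
    stop("negative NOD: exposed pixel value exceeds the unexposed reference (miscalibration?)",
         call. = FALSE)
  }
  log10(pv_unexposed / pv)
}

#' Build a monotone pixel-value to exposure calibration curve
#'
#' Film darkens with exposure, so pixel value must decrease strictly as
#' exposure increases; the calibration is interpolated with a monotone
#' (Fritsch-Carlson) piecewise cubic that passes through every point
#' exactly and cannot oscillate between them. Evaluation outside the
#' calibrated pixel-value range is refused, never extrapolated or clamped.
#'
#' @param points Data frame with columns `pixel_value` and `exposure_R`
#'   (at least 3 rows).
#' @return An object of class `calibration_curve`.
#' @export
build_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("pixel_value", "exposure_R") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (any(points$exposure_R < 0)) stop("exposure must be >= 0", call. = FALSE)
  if (any(points$pixel_value <= 0)) stop("pixel values must be > 0", call. = FALSE)
  if (anyDuplicated(points$pixel_value)) stop("duplicate pixel values", call. = FALSE)
  pts <- points[order(points$exposure_R), c("pixel_value", "exposure_R")]
  if (any(diff(pts$exposure_R) <= 0)) stop("duplicate exposure values", call. = FALSE)
  if (any(diff(pts$pixel_value) >= 0)) {
    stop("pixel value must decrease strictly as exposure increases (darkening film)",
         call. = FALSE)
  }
  asc <- pts[order(pts$pixel_value), ]
  structure(
    list(
      points = pts,
      pv_range = range(pts$pixel_value),
      exposure_range = range(pts$exposure_R),
      pv_to_exp = stats::splinefun(asc$pixel_value, asc$exposure_R, method = "monoH.FC"),
      exp_to_pv = stats::splinefun(pts$exposure_R, pts$pixel_value, method = "monoH.FC")
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %d points | PV [%g, %g] <-> exposure [%g, %g] R\n",
    nrow(x$points), x$pv_range[1], x$pv_range[2],
    x$exposure_range[1], x$exposure_range[2]
  ))
  invisible(x)
}

#' Convert pixel values to exposure through a calibration curve
#'
#' @param curve A [build_calibration()] curve.
#' @param pv Pixel values within the calibrated range.
#' @return Exposure in roentgen (R), monotone nonincreasing in `pv`.
#' @export
pv_to_exposure <- function(curve, pv) {
  stopifnot(inherits(curve, "calibration_curve"))
  eps <- 1e-9 * diff(curve$pv_range)
  if (any(pv < curve$pv_range[1] - eps | pv > curve$pv_range[2] + eps)) {
    stop(sprintf("extrapolation refused: pixel values outside calibrated range [%g, %g]",
                 curve$pv_range[1], curve$pv_range[2]), call. = FALSE)
  }
  pmax(0, curve$pv_to_exp(pmin(pmax(pv, curve$pv_range[1]), curve$pv_range[2])))
}

#' Convert exposure to pixel values (inverse calibration)
#'
#' Used to render synthetic film strips for round-trip validation.
#'
#' @param curve A [build_calibration()] curve.
#' @param exposure_R Exposure values within the calibrated range.
#' @return Pixel values.
#' @export
exposure_to_pv <- function(curve, exposure_R) {
  stopifnot(inherits(curve, "calibration_curve"))
  eps <- 1e-9 * diff(curve$exposure_range)
  if (any(exposure_R < curve$exposure_range[1] - eps |
          exposure_R > curve$exposure_range[2] + eps)) {
    stop(sprintf("extrapolation refused: exposures outside calibrated range [%g, %g] R",
                 curve$exposure_range[1], curve$exposure_range[2]), call. = FALSE)
  }
  curve$exp_to_pv(pmin(pmax(exposure_R, curve$exposure_range[1]),
                       curve$exposure_range[2]))
}

#' Convert exposure in air to absorbed dose
#'
#' `dose = exposure x 0.869 x 1.00` cGy: the roentgen-to-rad conversion for
#' air times the (unit) dose-to-air to dose-to-film factor.
#'
#' @param exposure_R Exposure in roentgen (>= 0).
#' @param roentgen_to_rad Conversion factor, rad/R.
#' @param dose_to_film Dose-to-air to dose-to-film factor.
#' @return Absorbed dose in cGy.
#' @examples
#' exposure_to_dose(1)  # 0.869
#' @export
exposure_to_dose <- function(exposure_R, roentgen_to_rad = .ROENTGEN_TO_RAD,
                             dose_to_film = .DOSE_TO_FILM) {
  if (any(exposure_R < 0)) stop("exposure must be >= 0", call. = FALSE)
  exposure_R * roentgen_to_rad * dose_to_film
}

#' Convert dose to exposure (inverse of [exposure_to_dose()])
#'
#' @param dose_cgy Absorbed dose in cGy.
#' @param roentgen_to_rad Conversion factor, rad/R.
#' @param dose_to_film Dose-to-air to dose-to-film factor.
#' @return Exposure in roentgen.
#' @export
dose_to_exposure <- function(dose_cgy, roentgen_to_rad = .ROENTGEN_TO_RAD,
                             dose_to_film = .DOSE_TO_FILM) {
  if (any(dose_cgy < 0)) stop("dose must be >= 0", call. = FALSE)
  dose_cgy / (roentgen_to_rad * dose_to_film)
}

# Red-channel pixel values per z position: mean over the lane rows (or
# columns when z runs along rows).
.lane_pv <- function(strip, lane) {
  red <- strip$image[, , 1]
  if (strip$z_axis == "rows") red <- t(red)
  if (is.null(lane)) lane <- seq_len(nrow(red))
  if (min(lane) < 1 || max(lane) > nrow(red)) {
    stop("lane outside image bounds", call. = FALSE)
  }
  colMeans(red[lane, , drop = FALSE])
}

#' Render a dose profile to a synthetic film strip
#'
#' The inverse of the film-analysis chain, used for round-trip validation:
#' dose -> exposure (dividing out the roentgen-to-rad factor) -> pixel
#' value through the inverted calibration curve, sampled at the pixel pitch
#' `25.4 / dpi` mm.
#'
#' @param profile A [dose_profile()].
#' @param curve A [build_calibration()] curve covering the profile's
#'   exposure range.
#' @param dpi Rendered scan resolution.
#' @param height_px Strip height in pixels.
#' @return A `film_strip` whose columns run along z starting at the
#'   profile's first grid point.
#' @export
render_film_strip <- function(profile, curve, dpi = 72, height_px = 24) {
  stopifnot(inherits(profile, "dose_profile"))
  pitch <- 25.4 / dpi
  z_px <- seq(min(profile$z_mm), max(profile$z_mm), by = pitch)
  dose <- stats::approx(profile$z_mm, profile$dose_cgy, z_px)$y
  pv <- exposure_to_pv(curve, dose_to_exposure(dose))
  img <- array(rep(pv, each = height_px), dim = c(height_px, length(pv), 3))
  film_strip(img, dpi = dpi, z_axis = "columns")
}

#' Extract a normalized axial dose profile from a film strip
#'
#' Lane-averaged red pixel values are converted to exposure through the
#' calibration curve and then to dose; the z coordinate follows from the
#' scan resolution (`z = pixel * 25.4 / dpi`), recentered at the centroid
#' of the profile's peak region (samples above half maximum); the profile
#' is divided by its central (z = 0) value so dose(0) = 1.
#'
#' @param strip A `film_strip`.
#' @param curve A [build_calibration()] curve covering the strip's pixel
#'   values.
#' @param lane Integer row indices (perpendicular to z) to average over;
#'   `NULL` for all.
#' @return A [dose_profile()] normalized to its central value, with
#'   `position = "film"`.
#' @export
extract_normalized_profile <- function(strip, curve, lane = NULL) {
  stopifnot(inherits(strip, "film_strip"), inherits(curve, "calibration_curve"))
  pv <- .lane_pv(strip, lane)
  eps <- 1e-9 * diff(curve$pv_range)
  bad <- which(pv < curve$pv_range[1] - eps | pv > curve$pv_range[2] + eps)
  if (length(bad)) {
    stop(sprintf(
      "pixel values outside calibration at %d column(s): %s",
      length(bad), paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  dose <- exposure_to_dose(pv_to_exposure(curve, pv))
  pitch <- 25.4 / strip$dpi
  z <- (seq_along(dose) - 1) * pitch
  peak <- dose >= max(dose) / 2
  z <- z - sum(z[peak] * dose[peak]) / sum(dose[peak])
  dose0 <- stats::approx(z, dose, 0)$y
  if (!is.finite(dose0) || dose0 <= 0) {
    stop("central (z = 0) dose is not positive; cannot normalize", call. = FALSE)
  }
  dose_profile(z, dose / dose0, position = "film")
}

#' Measure beam width as the profile's FWHM
#'
#' Distance between the outermost half-maximum crossings, with linear
#' interpolation between samples. Free-in-air strip profiles measured this
#' way verify the console's actual collimation settings.
#'
#' @param profile A [dose_profile()].
#' @return Full width at half maximum, mm.
#' @export
measure_beam_width_fwhm <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  z <- profile$z_mm
  d <- profile$dose_cgy
  half <- max(d) / 2
  above <- d >= half
  if (above[1] || above[length(d)] || !any(above)) {
    stop("profile does not rise above and fall below half maximum on both sides",
         call. = FALSE)
  }
  i1 <- which(above)[1]                    # first sample at/above half
  i2 <- rev(which(above))[1]               # last sample at/above half
  cross <- function(ia, ib) {              # linear crossing between samples
    z[ia] + (half - d[ia]) * (z[ib] - z[ia]) / (d[ib] - d[ia])
  }
  left <- if (d[i1] == half) z[i1] else cross(i1 - 1, i1)
  right <- if (d[i2] == half) z[i2] else cross(i2 + 1, i2)
  right - left
}
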