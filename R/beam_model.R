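# Scan-protocol and collimation bookkeeping.
#
# The collimation tables are measured calibration data for the modeled
# OBI-class scanner: the system collimates 1-3 cm wider than the nominal
# (console) reconstruction width, and no collimator geometry is available,
# so values between the ten calibrated settings are refused rather than
# interpolated.

# nominal console setting (cm) -> actual aperture at isocenter (mm)
.beam_width_tables <- list(
  full_fan = c(20, 34, 46, 60, 72, 84, 98, 110, 124, 136),
  half_fan = c(22, 38, 52, 66, 80, 96, 110, 124, 138, 154)
)

.fan_modes <- c("full_fan", "half_fan")

#' Construct a CBCT scan protocol
#'
#' A scan protocol bundles the acquisition metadata needed by the dose
#' statistics: fan mode, phantom, tube settings, number of projections per
#' rotation, the longitudinal integration range `l`, and the depth of the
#' peripheral measurement positions.
#'
#' Defaults follow the clinical CBCT technique the package models: 125 kVp,
#' 80 mA, 660 projections per rotation; full-fan scans pair with the 16 cm
#' head PMMA phantom and `l = 600` mm, half-fan scans with the 32 cm body
#' phantom and `l = 900` mm. Any field can be overridden explicitly.
#'
#' @param fan_mode `"full_fan"` (head) or `"half_fan"` (body).
#' @param phantom Phantom identifier; defaults to `"head_16cm"` for full-fan
#'   and `"body_32cm"` for half-fan.
#' @param tube_potential_kvp Tube potential in kVp.
#' @param tube_current_ma Tube current in mA.
#' @param projections Number of projections per rotation.
#' @param integration_range_l_mm Longitudinal integration range `l` in mm.
#' @param peripheral_depth_mm Depth of the four peripheral measurement
#'   positions below the phantom surface, in mm.
#' @return An object of class `scan_protocol`.
#' @examples
#' scan_protocol("full_fan")
#' scan_protocol("half_fan", integration_range_l_mm = 300)
#' @export
scan_protocol <- function(fan_mode = c("full_fan", "half_fan"),
                          phantom = NULL,
                          tube_potential_kvp = 125,
                          tube_current_ma = 80,
                          projections = 660,
                          integration_range_l_mm = NULL,
                          peripheral_depth_mm = 10) {
  fan_mode <- match.arg(fan_mode)
  if (is.null(phantom)) {
    phantom <- if (fan_mode == "full_fan") "head_16cm" else "body_32cm"
  }
  phantom <- match.arg(phantom, c("head_16cm", "body_32cm"))
  if (is.null(integration_range_l_mm)) {
    integration_range_l_mm <- if (fan_mode == "full_fan") 600 else 900
  }
  stopifnot(is.numeric(integration_range_l_mm), length(integration_range_l_mm) == 1)
  if (integration_range_l_mm <= 0) {
    stop("integration_range_l_mm must be > 0", call. = FALSE)
  }
  if (!is.numeric(projections) || length(projections) != 1 || projections <= 0) {
    stop("projections must be a positive count", call. = FALSE)
  }
  if (peripheral_depth_mm <= 0) {
    stop("peripheral_depth_mm must be > 0", call. = FALSE)
  }
  structure(
    list(
      fan_mode = fan_mode,
      phantom = phantom,
      tube_potential_kvp = tube_potential_kvp,
      tube_current_ma = tube_current_ma,
      projections = as.integer(projections),
      integration_range_l_mm = integration_range_l_mm,
      peripheral_depth_mm = peripheral_depth_mm
    ),
    class = "scan_protocol"
  )
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> %s / %s | %g kVp, %g mA, %d projections | l = %g mm\n",
    x$fan_mode, x$phantom, x$tube_potential_kvp, x$tube_current_ma,
    x$projections, x$integration_range_l_mm
  ))
  invisible(x)
}

#' Beam collimation descriptor
#'
#' Pairs a nominal (console) beam width with the physical aperture `T` at
#' isocenter. The aperture is always wider than the nominal width on the
#' modeled system, which the constructor enforces.
#'
#' @param nominal_width_cm Console setting in cm (1-10).
#' @param actual_width_mm Physical aperture at isocenter in mm.
#' @return An object of class `beam_collimation`.
#' @seealso [actual_beam_width()] for the calibrated lookup.
#' @export
beam_collimation <- function(nominal_width_cm, actual_width_mm) {
  stopifnot(length(nominal_width_cm) == 1, length(actual_width_mm) == 1)
  if (actual_width_mm <= 0) {
    stop("actual_width_mm must be > 0", call. = FALSE)
  }
  if (actual_width_mm < 10 * nominal_width_cm) {
    stop("actual_width_mm must be at least the nominal width (collimation is wider than nominal)",
         call. = FALSE)
  }
  structure(
    list(nominal_width_cm = nominal_width_cm, actual_width_mm = actual_width_mm),
    class = "beam_collimation"
  )
}

#' @export
print.beam_collimation <- function(x, ...) {
  cat(sprintf("<beam_collimation> nominal %g cm -> actual %g mm\n",
              x$nominal_width_cm, x$actual_width_mm))
  invisible(x)
}

#' Look up the actual beam width for a nominal console setting
#'
#' Returns the measured physical aperture at isocenter for a nominal
#' (console) beam width of 1-10 cm, per fan mode. The lookup is a fixed
#' calibration table; settings outside the calibrated grid are refused, not
#' extrapolated.
#'
#' @param protocol A [scan_protocol()] (only `fan_mode` is used).
#' @param nominal_width_cm Integer nominal width in cm, 1-10.
#' @return Actual beam width `T` in mm.
#' @examples
#' actual_beam_width(scan_protocol("full_fan"), 1)   # 20 mm
#' actual_beam_width(scan_protocol("half_fan"), 10)  # 154 mm
#' @export
actual_beam_width <- function(protocol, nominal_width_cm) {
  stopifnot(inherits(protocol, "scan_protocol"))
  tbl <- .beam_width_tables[[protocol$fan_mode]]
  if (length(nominal_width_cm) != 1 || is.na(nominal_width_cm) ||
      nominal_width_cm != as.integer(nominal_width_cm) ||
      nominal_width_cm < 1 || nominal_width_cm > length(tbl)) {
    stop(sprintf("no calibration entry for nominal width %s cm (calibrated: 1-10 cm)",
                 format(nominal_width_cm)), call. = FALSE)
  }
  tbl[[as.integer(nominal_width_cm)]]
}

#' Calibrated nominal beam widths
#'
#' @return Integer vector of console settings (cm) with calibration entries.
#' @export
nominal_beam_widths <- function() seq_along(.beam_width_tables$full_fan)
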