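# Cone-beam CTDI statistics: dose-profile integrals, aperture-normalized
# and weighted CTDI, mean weighted CTDI, DLP, truncated pencil-chamber
# indices, central ray dose, and report assembly.

#' Round half away from zero
#'
#' Report rounding as printed dose tables use it: halves round up
#' (8.495 -> 8.50 at 2 decimals), unlike [round()]'s round-half-even. A
#' small guard absorbs binary floating-point representation error so that
#' values that are exact halves in decimal arithmetic round up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' CTDI computation configuration
#'
#' @param integration_range_l_mm Longitudinal integration range `l`, mm.
#' @param weights Two nonnegative weights `(center, periphery)` summing to
#'   1. Default `c(0.5, 0.5)` (the Bakalyar coefficients); the conventional
#'   CT weighting `c(1/3, 2/3)` is available for cross-checks.
#' @param nominal_collimation_nt_mm The `n*T` divisor (mm) for the
#'   pencil-chamber indices CTDI100/CTDI300; `NULL` unless those are used.
#' @param decimals Decimal places for report output (printed dose tables use
#'   2).
#' @return An object of class `ctdi_config`.
#' @export
ctdi_config <- function(integration_range_l_mm, weights = c(0.5, 0.5),
                        nominal_collimation_nt_mm = NULL, decimals = 2) {
  if (integration_range_l_mm <= 0) stop("integration_range_l_mm must be > 0", call. = FALSE)
  .check_weights(weights)
  structure(
    list(
      integration_range_l_mm = integration_range_l_mm,
      weights = weights,
      nominal_collimation_nt_mm = nominal_collimation_nt_mm,
      decimals = decimals
    ),
    class = "ctdi_config"
  )
}

.check_weights <- function(weights) {
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be two nonnegative values summing to 1", call. = FALSE)
  }
  invisible(weights)
}

#' Dose-profile integral DPI_l
#'
#' Trapezoidal integral of the axial dose profile over `[-l/2, l/2]`, with
#' the endpoint values obtained by linear interpolation when `l/2` falls
#' between samples.
#'
#' @param profile A [dose_profile()].
#' @param l_mm Integration range `l` in mm; the profile grid must cover
#'   `[-l/2, l/2]`.
#' @return Integral in cGy·mm.
#' @examples
#' p <- generate_profile(40, scatter_params(1, 0, 50))
#' dpi(p, 600)  # 40: rectangle height 1, width 40
#' @export
dpi <- function(profile, l_mm) {
  stopifnot(inherits(profile, "dose_profile"))
  if (l_mm <= 0) stop("l_mm must be > 0", call. = FALSE)
  z <- profile$z_mm
  d <- profile$dose_cgy
  a <- -l_mm / 2
  b <- l_mm / 2
  eps <- 1e-9 * profile$spacing_mm
  if (a < z[1] - eps || b > z[length(z)] + eps) {
    stop(sprintf("range not covered: profile spans [%g, %g] mm but l/2 = %g mm",
                 z[1], z[length(z)], b), call. = FALSE)
  }
  a <- max(a, z[1]); b <- min(b, z[length(z)])
  inside <- z > a & z < b
  zz <- c(a, z[inside], b)
  dd <- c(stats::approx(z, d, a)$y, d[inside], stats::approx(z, d, b)$y)
  sum(diff(zz) * (dd[-length(dd)] + dd[-1]) / 2)
}

#' Aperture-normalized cone-beam CTDI
#'
#' `CTDI_a,l = DPI_l / T`, dividing by the actual (physical) beam width `T`
#' rather than the nominal width. At equilibrium (l spanning the full
#' profile) this quantity is constant across apertures.
#'
#' @param profile A [dose_profile()].
#' @param l_mm Integration range, mm.
#' @param T_mm Actual beam width, mm; defaults to the profile's own.
#' @return CTDI_a,l in cGy (DPI in cGy·mm divided by T in mm).
#' @export
ctdi_a <- function(profile, l_mm, T_mm = profile$beam_width_mm) {
  if (is.na(T_mm) || T_mm <= 0) stop("T_mm must be > 0", call. = FALSE)
  dpi(profile, l_mm) / T_mm
}

#' Weighted cone-beam CTDI
#'
#' Combines the central-axis value with the mean of the four peripheral
#' values: `w_c * center + w_p * mean(periphery)`, default weights
#' (1/2, 1/2).
#'
#' @param center_cgy Central-axis CTDI_a (or point dose), cGy.
#' @param periphery_cgy The four peripheral values, or a single
#'   pre-averaged peripheral value, cGy.
#' @param weights Two nonnegative weights `(center, periphery)` summing
#'   to 1.
#' @return Weighted CTDI in cGy (full precision; round for reporting).
#' @examples
#' ctdi_w(8.78, 8.21)  # 8.495 -> prints as 8.50
#' @export
ctdi_w <- function(center_cgy, periphery_cgy, weights = c(0.5, 0.5)) {
  .check_weights(weights)
  stopifnot(length(center_cgy) == 1)
  if (!length(periphery_cgy) %in% c(1L, 4L)) {
    stop("periphery_cgy must hold 4 values or 1 pre-averaged value", call. = FALSE)
  }
  weights[1] * center_cgy + weights[2] * mean(periphery_cgy)
}

#' Mean and spread of weighted CTDI across beam widths
#'
#' Arithmetic mean and sample standard deviation of per-beam-width weighted
#' CTDI values; the mean is the scan protocol's single representative dose
#' index.
#'
#' @param ctdi_w_cgy Numeric vector of weighted CTDI values, one per beam
#'   width.
#' @return List with elements `mean` and `sd` (cGy); `sd` is `NA` for a
#'   single value.
#' @export
mean_ctdi_w <- function(ctdi_w_cgy) {
  if (length(ctdi_w_cgy) == 0) stop("no CTDI_w values supplied", call. = FALSE)
  list(mean = mean(ctdi_w_cgy),
       sd = if (length(ctdi_w_cgy) > 1) stats::sd(ctdi_w_cgy) else NA_real_)
}

#' Dose-length product
#'
#' `DLP = mean CTDI_w * T`, with `T` converted to cm so DLP is in cGy·cm.
#'
#' @param mean_ctdi_w_cgy Mean weighted CTDI, cGy (pass the report-rounded
#'   mean to reproduce printed tables).
#' @param T_mm Actual beam width, mm.
#' @return DLP in cGy·cm.
#' @examples
#' dlp(8.74, 136)  # 118.864 -> prints as 118.86
#' @export
dlp <- function(mean_ctdi_w_cgy, T_mm) {
  if (any(mean_ctdi_w_cgy < 0) || any(T_mm < 0)) stop("inputs must be >= 0", call. = FALSE)
  mean_ctdi_w_cgy * T_mm / 10
}

#' Truncated pencil-chamber dose indices
#'
#' The fixed-range indices measurable with 100 mm and 300 mm pencil
#' ionization chambers: `ctdi100 = DPI(100 mm)/nT`,
#' `d100 = DPI(100 mm)/100` (average absorbed dose within the chamber), and
#' `ctdi300 = DPI(300 mm)/nT`. For wide cone beams with long scatter tails
#' these strictly underestimate the full-range aperture-normalized CTDI.
#'
#' @param profile A [dose_profile()].
#' @param variant `"ctdi100"`, `"d100"` or `"ctdi300"`.
#' @param nominal_collimation_nt_mm The `n*T` divisor in mm (required for
#'   `ctdi100` and `ctdi300`).
#' @return Index value in cGy.
#' @export
ctdi_truncated <- function(profile, variant = c("ctdi100", "d100", "ctdi300"),
                           nominal_collimation_nt_mm = NULL) {
  variant <- match.arg(variant)
  if (variant %in% c("ctdi100", "ctdi300") &&
      (is.null(nominal_collimation_nt_mm) || nominal_collimation_nt_mm <= 0)) {
    stop("nominal_collimation_nt_mm is required for ", variant, call. = FALSE)
  }
  switch(variant,
         ctdi100 = dpi(profile, 100) / nominal_collimation_nt_mm,
         d100 = dpi(profile, 100) / 100,
         ctdi300 = dpi(profile, 300) / nominal_collimation_nt_mm)
}

#' Central ray dose f(0)
#'
#' The axial profile's value at `z = 0` (linearly interpolated when 0 falls
#' between samples) -- the accumulated peak dose, and the quantity a point
#' dose measurement with a small chamber estimates.
#'
#' @param profile A [dose_profile()].
#' @return Dose at z = 0, cGy.
#' @export
f0 <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  z <- profile$z_mm
  if (0 < z[1] || 0 > z[length(z)]) stop("z = 0 outside profile grid", call. = FALSE)
  stats::approx(z, profile$dose_cgy, 0)$y
}

#' Percent difference from a reference value
#'
#' `|other - reference| / reference * 100`, rounded for reporting.
#'
#' @param reference Reference value (> 0).
#' @param other Comparison value.
#' @param decimals Decimal places for the reported percentage.
#' @return Percent difference.
#' @examples
#' percent_difference(8.50, 8.77)  # 3.2
#' @export
percent_difference <- function(reference, other, decimals = 1) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  round_half_up(abs(other - reference) / reference * 100, decimals)
}

#' Assemble a per-beam-width CTDI report
#'
#' For each profile set: integrates center and peripheral profiles over the
#' configured range to CTDI_a,l, combines them to the weighted CTDI, and
#' records the central ray dose. Scan-level quantities follow: the mean
#' weighted CTDI (with sample SD) across beam widths, and per-row
#' `DLP = mean CTDI_w * T`. The DPI column is the weighted integral,
#' `CTDI_w,l * T`, which tracks DLP row by row. DLP is computed from the
#' report-precision (rounded) mean, matching how printed dose tables are
#' assembled; all other columns are kept at full precision until printed.
#'
#' @param profile_sets List of `profile_set` objects sharing one protocol.
#' @param config A [ctdi_config()]; defaults to the shared protocol's
#'   integration range with (1/2, 1/2) weights.
#' @return An object of class `ctdi_report` with element `rows` (data frame
#'   `beam_width_mm, dpi_cGycm, ctdi_w_cGy, dlp_cGycm, f0_cGy`),
#'   `mean_ctdi_w`, `mean_ctdi_w_sd`, `protocol`, `config`.
#' @export
build_report <- function(profile_sets, config = NULL) {
  if (inherits(profile_sets, "profile_set")) profile_sets <- list(profile_sets)
  if (length(profile_sets) == 0) stop("no profile sets supplied", call. = FALSE)
  stopifnot(all(vapply(profile_sets, inherits, logical(1), "profile_set")))
  proto <- profile_sets[[1]]$protocol
  for (s in profile_sets) {
    if (!identical(unclass(s$protocol), unclass(proto))) {
      stop("all profile sets must share one scan protocol", call. = FALSE)
    }
  }
  if (is.null(config)) config <- ctdi_config(proto$integration_range_l_mm)
  l <- config$integration_range_l_mm

  rows <- lapply(profile_sets, function(s) {
    T_mm <- s$collimation$actual_width_mm
    center <- ctdi_a(s$profiles$center, l, T_mm)
    periph <- vapply(
      s$profiles[setdiff(names(s$profiles), "center")],
      ctdi_a, numeric(1), l_mm = l, T_mm = T_mm
    )
    cw <- ctdi_w(center, periph, config$weights)
    data.frame(
      beam_width_mm = T_mm,
      dpi_cGycm = cw * T_mm / 10,
      ctdi_w_cGy = cw,
      f0_cGy = f0(s$profiles$center)
    )
  })
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$beam_width_mm), , drop = FALSE]
  rownames(rows) <- NULL

  m <- mean_ctdi_w(rows$ctdi_w_cGy)
  mean_report <- round_half_up(m$mean, config$decimals)
  rows$dlp_cGycm <- dlp(mean_report, rows$beam_width_mm)
  rows <- rows[c("beam_width_mm", "dpi_cGycm", "ctdi_w_cGy", "dlp_cGycm", "f0_cGy")]

  structure(
    list(rows = rows, mean_ctdi_w = m$mean, mean_ctdi_w_sd = m$sd,
         protocol = proto, config = config),
    class = "ctdi_report"
  )
}

#' Build a report directly from weighted CTDI values
#'
#' Constructs the report scaffold (mean CTDI_w, DLP and weighted-DPI
#' columns) from already-computed per-beam-width weighted CTDI values --
#' the path used when reproducing a published dose table or combining
#' point-dose measurements.
#'
#' @param ctdi_w_cgy Weighted CTDI per beam width, cGy.
#' @param beam_width_mm Actual beam widths, mm (same length).
#' @param decimals Report precision used for the mean entering DLP.
#' @return A `ctdi_report` (without `f0` column, `protocol = NULL`).
#' @export
report_from_ctdi_w <- function(ctdi_w_cgy, beam_width_mm, decimals = 2) {
  stopifnot(length(ctdi_w_cgy) == length(beam_width_mm),
            length(ctdi_w_cgy) >= 1)
  m <- mean_ctdi_w(ctdi_w_cgy)
  mean_report <- round_half_up(m$mean, decimals)
  rows <- data.frame(
    beam_width_mm = beam_width_mm,
    dpi_cGycm = ctdi_w_cgy * beam_width_mm / 10,
    ctdi_w_cGy = ctdi_w_cgy,
    dlp_cGycm = dlp(mean_report, beam_width_mm),
    f0_cGy = NA_real_
  )
  structure(
    list(rows = rows, mean_ctdi_w = m$mean, mean_ctdi_w_sd = m$sd,
         protocol = NULL, config = ctdi_config(1, decimals = decimals)),
    class = "ctdi_report"
  )
}

#' @export
print.ctdi_report <- function(x, ...) {
  cat("<ctdi_report>")
  if (!is.null(x$protocol)) cat(sprintf(" %s, l = %g mm", x$protocol$fan_mode,
                                        x$config$integration_range_l_mm))
  cat("\n")
  print(as.data.frame(x, rounded = TRUE))
  cat(sprintf("Mean CTDI_w: %s +- %s cGy\n",
              format(round_half_up(x$mean_ctdi_w, x$config$decimals)),
              format(signif(x$mean_ctdi_w_sd, 2))))
  invisible(x)
}

#' Report rows as a data frame
#'
#' @param x A `ctdi_report`.
#' @param rounded Round columns to the report precision (as a printed table
#'   would show them)?
#' @param ... Unused.
#' @export
as.data.frame.ctdi_report <- function(x, rounded = FALSE, ...) {
  rows <- x$rows
  if (rounded) {
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], round_half_up, digits = x$config$decimals)
  }
  rows
}
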