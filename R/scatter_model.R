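# Narrow-beam scatter model.
#
# A cone beam's axial dose profile is modeled as the superposition of
# narrow-beam profiles: the rectangle of the physical aperture convolved
# with a narrow-beam line-spread function (LSF). The LSF used here is the
# simplest kernel with the three behaviours wide-beam CT dosimetry
# exhibits -- exact aperture-normalized CTDI constancy, a central ray dose
# f(0) that saturates with beam width, and long scatter tails:
#
#   lsf(z) = (1 - eta) * g(z; sigma) + (eta / 2d) * exp(-|z| / d)
#
# with g a unit-area Gaussian (a Dirac impulse when sigma = 0). eta is the
# scatter fraction, d the scatter decay length; the kernel has unit area,
# so the profile integral is always h * T.

#' Scatter model parameters for one measurement position
#'
#' @param equilibrium_dose_h Plateau dose (cGy) an infinitely wide beam
#'   would deposit at this position; the profile's asymptotic central value.
#' @param scatter_fraction_eta Fraction of the deposited dose carried by the
#'   scatter tails, in `[0, 1)`.
#' @param scatter_range_d Exponential decay length of the scatter tails, mm.
#' @param penumbra_sigma Gaussian blur (mm) of the aperture edges; 0 keeps
#'   the primary core a sharp rectangle.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   applied per sample (0 = noiseless).
#' @return An object of class `scatter_params`.
#' @examples
#' scatter_params(8.8, 0.6, 60)
#' @export
scatter_params <- function(equilibrium_dose_h, scatter_fraction_eta,
                           scatter_range_d, penumbra_sigma = 0,
                           noise_cv = 0) {
  if (equilibrium_dose_h <= 0) stop("equilibrium_dose_h must be > 0", call. = FALSE)
  if (scatter_fraction_eta < 0 || scatter_fraction_eta >= 1) {
    stop("scatter_fraction_eta must be in [0, 1)", call. = FALSE)
  }
  if (scatter_range_d <= 0) stop("scatter_range_d must be > 0", call. = FALSE)
  if (penumbra_sigma < 0) stop("penumbra_sigma must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(
    list(
      equilibrium_dose_h = equilibrium_dose_h,
      scatter_fraction_eta = scatter_fraction_eta,
      scatter_range_d = scatter_range_d,
      penumbra_sigma = penumbra_sigma,
      noise_cv = noise_cv
    ),
    class = "scatter_params"
  )
}

#' @export
print.scatter_params <- function(x, ...) {
  cat(sprintf(
    "<scatter_params> h = %g cGy, eta = %g, d = %g mm, sigma = %g mm, noise CV = %g\n",
    x$equilibrium_dose_h, x$scatter_fraction_eta, x$scatter_range_d,
    x$penumbra_sigma, x$noise_cv
  ))
  invisible(x)
}

#' Default scatter parameters per scan type and position
#'
#' Illustrative (not fitted) parameter sets chosen to land in the
#' qualitative range of clinical head and body CBCT dose tables: central
#' profiles are broader (larger `eta` and `d`) than peripheral ones, and the
#' body center sits well below its periphery. Real-beam parameters are
#' configuration, not constants.
#'
#' @param scan `"head"` or `"body"`.
#' @param position `"center"` or `"periphery"`.
#' @param noise_cv Noise coefficient of variation (default 0.01, the
#'   sub-percent statistical uncertainty regime of well-converged Monte
#'   Carlo profiles).
#' @return A [scatter_params()] object.
#' @export
default_scatter_params <- function(scan = c("head", "body"),
                                   position = c("center", "periphery"),
                                   noise_cv = 0.01) {
  scan <- match.arg(scan)
  position <- match.arg(position)
  p <- switch(
    paste(scan, position, sep = "."),
    head.center    = list(h = 8.8, eta = 0.60, d = 60),
    head.periphery = list(h = 8.8, eta = 0.45, d = 40),
    body.center    = list(h = 3.1, eta = 0.75, d = 90),
    body.periphery = list(h = 5.5, eta = 0.50, d = 60)
  )
  scatter_params(p$h, p$eta, p$d, penumbra_sigma = 0, noise_cv = noise_cv)
}

#' Narrow-beam line-spread function
#'
#' Evaluates the unit-area narrow-beam kernel
#' `(1 - eta) g(z; sigma) + (eta / 2d) exp(-|z| / d)`. When
#' `penumbra_sigma = 0` the primary term is a Dirac impulse; it is then
#' represented discretely as `(1 - eta) / spacing` at `z = 0`, so that the
#' sampled kernel still integrates to one on a uniform grid.
#'
#' @param z Axial positions in mm.
#' @param params A [scatter_params()] object.
#' @param spacing Grid spacing in mm; required to represent the impulse when
#'   `penumbra_sigma = 0` and any `z` equals 0.
#' @return Kernel density values (per mm), even in `z`.
#' @examples
#' p <- scatter_params(1, 0.4, 50)
#' narrow_beam_lsf(100, p)  # (0.4/100) * exp(-2)
#' @export
narrow_beam_lsf <- function(z, params, spacing = NULL) {
  stopifnot(inherits(params, "scatter_params"))
  eta <- params$scatter_fraction_eta
  d <- params$scatter_range_d
  sigma <- params$penumbra_sigma
  tail <- (eta / (2 * d)) * exp(-abs(z) / d)
  if (sigma > 0) {
    core <- (1 - eta) * stats::dnorm(z, sd = sigma)
  } else {
    core <- numeric(length(z))
    at0 <- z == 0
    if (any(at0)) {
      if (is.null(spacing)) {
        stop("spacing is required to represent the impulse core at z = 0 when penumbra_sigma = 0",
             call. = FALSE)
      }
      core[at0] <- (1 - eta) / spacing
    }
  }
  core + tail
}

#' Closed-form central ray dose f(0)
#'
#' For the impulse-core kernel (`penumbra_sigma = 0`) the central value of a
#' rectangle of width `T` convolved with the narrow-beam LSF is
#' `h * (1 - eta * exp(-T / (2 d)))`: monotone nondecreasing in `T` and
#' saturating at the equilibrium dose `h` as `T` grows. This is the analytic
#' oracle against which the numerical profile generator is tested.
#'
#' @param T_mm Actual beam width in mm.
#' @param params A [scatter_params()] object with `penumbra_sigma = 0`.
#' @return Central ray dose in cGy.
#' @examples
#' analytic_f0(20, scatter_params(1, 0.4, 50))  # 0.67254
#' @export
analytic_f0 <- function(T_mm, params) {
  stopifnot(inherits(params, "scatter_params"))
  if (params$penumbra_sigma > 0) {
    stop("no closed form for f(0) with penumbra_sigma > 0", call. = FALSE)
  }
  if (any(T_mm <= 0)) stop("T_mm must be > 0", call. = FALSE)
  h <- params$equilibrium_dose_h
  eta <- params$scatter_fraction_eta
  d <- params$scatter_range_d
  h * (1 - eta * exp(-T_mm / (2 * d)))
}
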