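rect_profile <- function(height = 1, width = 40, spacing = 0.5, half = 450) {
  z <- default_z_grid(spacing, half)
  dose_profile(z, height * (abs(z) < width / 2) +
                 0.5 * height * (abs(z) == width / 2),
               beam_width_mm = width)
}

test_that("dose-profile integral handles rectangles, zero dose and endpoints", {
  p <- rect_profile(1, 40)
  expect_equal(dpi(p, 600), 40)
  expect_equal(dpi(dose_profile(p$z_mm, rep(0, length(p$z_mm))), 600), 0)

  # endpoint interpolation when l/2 falls between samples: l = 30.6 on a
  # 1 mm grid clips the rectangle to exactly l
  z <- seq(-100, 100, 1)
  wide <- dose_profile(z, rep(2, length(z)))
  expect_equal(dpi(wide, 30.6), 2 * 30.6)

  expect_error(dpi(p, 2000), "range not covered")
  expect_error(dpi(p, -5), "> 0")
})

test_that("dpi and ctdi_a are linear in dose and monotone in range", {
  prm <- scatter_params(2, 0.5, 40)
  p <- generate_profile(60, prm)
  p3 <- dose_profile(p$z_mm, 3 * p$dose_cgy, beam_width_mm = 60)
  expect_equal(dpi(p3, 600), 3 * dpi(p, 600), tolerance = 1e-12)
  expect_equal(ctdi_a(p3, 600), 3 * ctdi_a(p, 600), tolerance = 1e-12)

  ls <- c(100, 200, 300, 600, 900)
  vals <- vapply(ls, dpi, numeric(1), profile = p)
  expect_true(all(diff(vals) > 0))
})

test_that("trapezoidal dpi agrees with the closed-form integral", {
  for (eta in c(0.3, 0.6)) {
    for (d in c(40, 80)) {
      p <- generate_profile(72, scatter_params(1, eta, d))
      for (l in c(100, 300, 600)) {
        expect_equal(dpi(p, l), oracle_dpi(1, eta, d, 72, l),
                     tolerance = 1e-3,
                     label = sprintf("dpi(eta=%g,d=%g,l=%g)", eta, d, l))
      }
    }
  }
})

test_that("aperture-normalized CTDI is constant across beam widths at equilibrium", {
  # scatter-free rectangle: exactly 1 for any width
  for (T in c(20, 72, 136)) {
    p <- generate_profile(T, scatter_params(1, 0, 50))
    expect_equal(ctdi_a(p, 600), 1, tolerance = 1e-9)
  }
  # with scatter, full-grid integration recovers h independent of T
  prm <- scatter_params(8.8, 0.6, 60)
  Ts <- c(20, 34, 46, 60, 72, 84, 98, 110, 124, 136)
  vals <- vapply(Ts, function(T) ctdi_a(generate_profile(T, prm), 900),
                 numeric(1))
  expect_equal(vals, rep(8.8, 10), tolerance = 1e-3)
  expect_lt(sd(vals) / mean(vals), 1e-3)

  expect_error(ctdi_a(rect_profile(), 600, T_mm = 0), "> 0")
})

test_that("weighted CTDI combines center and periphery as published", {
  # printed point-dose rows: f(0) center with pre-averaged periphery
  expect_equal(round_half_up(ctdi_w(8.78, 8.21), 2), 8.50)
  expect_equal(round_half_up(ctdi_w(8.77, 8.76), 2), 8.77)
  expect_equal(round_half_up(ctdi_w(3.09, 5.32), 2), 4.21)
  expect_equal(round_half_up(ctdi_w(3.08, 5.44), 2), 4.26)

  # four explicit peripheral values; degenerate equal case
  expect_equal(ctdi_w(6, c(4, 5, 6, 7)), 0.5 * 6 + 0.5 * 5.5)
  expect_equal(ctdi_w(3.7, rep(3.7, 4)), 3.7)
  expect_equal(ctdi_w(3.7, rep(3.7, 4), weights = c(1 / 3, 2 / 3)), 3.7)

  # weighted value bounded by min/max of inputs
  set.seed(1)
  for (i in 1:20) {
    ctr <- runif(1, 1, 10); per <- runif(4, 1, 10)
    w <- ctdi_w(ctr, per)
    expect_gte(w, min(ctr, per))
    expect_lte(w, max(ctr, per))
  }

  expect_error(ctdi_w(1, c(1, 2)), "4 values or 1")
  expect_error(ctdi_w(1, 1, weights = c(0.6, 0.6)), "summing to 1")
})

test_that("mean weighted CTDI reproduces the published scan means", {
  head <- c(8.73, 8.75, 8.75, 8.75, 8.75, 8.74, 8.75, 8.74, 8.73, 8.72)
  body <- c(4.26, 4.26, 4.26, 4.27, 4.27, 4.26, 4.27, 4.26, 4.26, 4.25)
  mh <- mean_ctdi_w(head)
  mb <- mean_ctdi_w(body)
  expect_equal(round_half_up(mh$mean, 2), 8.74)
  expect_equal(round_half_up(mb$mean, 2), 4.26)
  # the published +-0.01 spread
  expect_lt(mh$sd, 0.015)
  expect_lt(mb$sd, 0.015)

  expect_equal(mean_ctdi_w(rep(5, 4)), list(mean = 5, sd = 0))
  expect_error(mean_ctdi_w(numeric(0)), "no CTDI_w")
})

test_that("DLP converts the mean index and width to cGy cm", {
  expect_equal(round_half_up(dlp(8.74, 136), 2), 118.86)
  expect_equal(round_half_up(dlp(4.26, 80), 2), 34.08)
  expect_equal(dlp(8.74, 0), 0)
  expect_error(dlp(-1, 20), ">= 0")
})

test_that("truncated pencil-chamber indices behave like their definitions", {
  p <- rect_profile(1, 40)
  expect_equal(ctdi_truncated(p, "ctdi100", nominal_collimation_nt_mm = 40), 1)
  expect_equal(ctdi_truncated(p, "d100"), 40 / 100)
  # D100bar = (nT/100) * CTDI100 identity
  expect_equal(ctdi_truncated(p, "d100"),
               40 / 100 * ctdi_truncated(p, "ctdi100", nominal_collimation_nt_mm = 40))

  # wide beam with long tails: strict underestimation ladder
  wide <- generate_profile(136, scatter_params(8.8, 0.6, 60))
  c100 <- ctdi_truncated(wide, "ctdi100", nominal_collimation_nt_mm = 136)
  c300 <- ctdi_truncated(wide, "ctdi300", nominal_collimation_nt_mm = 136)
  full <- ctdi_a(wide, 900)
  expect_lt(c100, c300)
  expect_lt(c300, full)

  expect_error(ctdi_truncated(p, "ctdi100"), "required")
})

test_that("central ray dose reads the profile at z = 0", {
  expect_equal(f0(rect_profile(2.5, 40)), 2.5)
  p <- generate_profile(20, scatter_params(1, 0.4, 50))
  expect_equal(f0(p), 0.67254, tolerance = 1e-3)
  # interpolation when 0 is between samples (linear ramp -> exact)
  z <- seq(-10.5, 10.5, 1)
  expect_equal(f0(dose_profile(z, 2 + z / 100)), 2)
})

test_that("percent difference matches the published method comparison", {
  expect_equal(percent_difference(8.50, 8.77), 3.2)
  expect_equal(percent_difference(4.21, 4.26), 1.2)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 1), "> 0")
})

test_that("build_report assembles rows, mean and DLP consistently", {
  proto <- scan_protocol("full_fan")
  mk <- function(nw, cp, pp, cv = 0) {
    generate_profile_set(proto, beam_collimation(nw, actual_beam_width(proto, nw)),
                         cp, pp, seed = nw, noise_cv = cv)
  }

  # scatter-free h=1 everywhere: every row has ctdi_w = 1, dlp = T/10
  flat <- scatter_params(1, 0, 50)
  sets <- lapply(c(2, 5, 8), mk, cp = flat, pp = flat)
  rep1 <- build_report(sets)
  expect_equal(rep1$rows$ctdi_w_cGy, rep(1, 3), tolerance = 1e-9)
  expect_equal(rep1$rows$dlp_cGycm, rep1$rows$beam_width_mm / 10, tolerance = 1e-9)
  expect_equal(rep1$mean_ctdi_w, 1, tolerance = 1e-9)

  # DLP / T constant across rows by construction
  expect_equal(length(unique(round(rep1$rows$dlp_cGycm / rep1$rows$beam_width_mm, 9))), 1)

  # parameter recovery: noiseless synthetic set, l well beyond T + 16 d
  cp <- scatter_params(8.8, 0.5, 20)
  pp <- scatter_params(8.2, 0.45, 18)
  sets2 <- lapply(c(1, 4, 7, 10), mk, cp = cp, pp = pp)
  rep2 <- build_report(sets2, ctdi_config(800))
  expect_equal(rep2$mean_ctdi_w, 0.5 * (8.8 + 8.2), tolerance = 2e-3)
  expect_lt(rep2$mean_ctdi_w_sd, 0.001 * rep2$mean_ctdi_w)
  expect_true(all(diff(rep2$rows$f0_cGy) > 0))

  # protocols must match across sets
  other <- generate_profile_set(scan_protocol("half_fan"), beam_collimation(2, 38),
                                default_scatter_params("body", "center"),
                                default_scatter_params("body", "periphery"), seed = 1)
  expect_error(build_report(c(sets2, list(other))), "share one scan protocol")
  expect_error(build_report(list()), "no profile sets")
})
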