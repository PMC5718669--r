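# Independent closed-form oracles for the scatter-convolution model,
# derived by direct piecewise integration of rect(T) (x) kernel; they never
# call the package's profile generator.

# exponential-tail contribution of rect(T) convolved with (eta/2d) e^{-|z|/d}
oracle_exp_tail <- function(z, eta, d, T) {
  za <- abs(z)
  ifelse(
    za <= T / 2,
    (eta / 2) * (2 - exp(-(T / 2 - za) / d) - exp(-(T / 2 + za) / d)),
    (eta / 2) * (exp(-(za - T / 2) / d) - exp(-(za + T / 2) / d))
  )
}

# full noiseless profile for the impulse-core (sigma = 0) kernel
oracle_profile <- function(z, h, eta, d, T) {
  h * ((1 - eta) * (abs(z) < T / 2) + oracle_exp_tail(z, eta, d, T))
}

# central ray dose of the sigma = 0 model
oracle_f0 <- function(h, eta, d, T) h * (1 - eta * exp(-T / (2 * d)))

# exact integral of the sigma = 0 model over [-l/2, l/2]
# (rect part: min(l, T); tail part by integrating oracle_exp_tail)
oracle_dpi <- function(h, eta, d, T, l) {
  b <- l / 2
  core <- (1 - eta) * min(l, T)
  if (b <= T / 2) {
    tail <- eta * (2 * b - d * exp(-T / (2 * d)) * (exp(b / d) - exp(-b / d)))
  } else {
    inside <- eta * (T - d * (1 - exp(-T / d)))
    # outer branch from T/2 to b, both sides:
    # 2 * int (eta/2)(e^{-(z-T/2)/d} - e^{-(z+T/2)/d}) dz
    outside <- eta * d * ((1 - exp(-(b - T / 2) / d)) -
                            (exp(-T / d) - exp(-(b + T / 2) / d)))
    tail <- inside + outside
  }
  h * (core + tail)
}
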