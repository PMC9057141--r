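# Independent numerical oracles used across test files. These never
# call the package's own convolution or model-evaluation paths.

# Voigt profile by adaptive quadrature of the defining integral
# (Gaussian x Lorentzian), accurate to ~1e-10 relative.
voigt_quad <- function(x, sigma, gamma) {
  vapply(x, function(xi) {
    stats::integrate(function(t) {
      stats::dnorm(t, 0, sigma) * (gamma / pi) / ((xi - t)^2 + gamma^2)
    }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1L))
}

# Temperature of the T1 minimum located by brute-force grid search on
# a dense noiseless curve.
grid_min_temperature <- function(model, t_range = c(20, 300), n = 20001L) {
  Tg <- seq(t_range[1L], t_range[2L], length.out = n)
  t1 <- 1 / model_rate(model, Tg)
  Tg[which.min(t1)]
}

# Maximizer of the reduced BPP rate by brute-force grid search.
grid_bpp_maximizer <- function(n = 2000001L) {
  x <- seq(1e-4, 5, length.out = n)
  f <- x / (1 + x^2) + 4 * x / (1 + 4 * x^2)
  x[which.max(f)]
}

make_instrument <- function(nq = 6L) {
  instrument_config(q_values = seq(0.3, 1.8, length.out = nq))
}
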