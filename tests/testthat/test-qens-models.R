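test_that("three-site EISF has its analytic values and limits", {
  expect_identical(eisf_three_site(0, 1.03), 1)
  expect_identical(eisf_three_site(0, 0.5), 1)
  # sin(pi) = 0 makes A0 = 1/3 where q r sqrt(3) = pi
  q_pi <- pi / (1.03 * sqrt(3))
  expect_equal(eisf_three_site(q_pi, 1.03), 1 / 3, tolerance = 1e-12)
  # frozen direct evaluation at the upper end of the Q range
  expect_equal(eisf_three_site(1.8, 1.03), 0.3189, tolerance = 1e-3)
  expect_error(eisf_three_site(-0.1, 1.03), "non-negative")
})

test_that("ideal three-site law preserves the sum rule and elastic limits", {
  og <- seq(-2, 2, length.out = 801L)
  # c = 1: purely elastic with weight amplitude * DW
  m1 <- three_site_model(gamma = 0.3, immobile_fraction = 1, msd = 0.04,
                         amplitude = 1.5)
  s1 <- ideal_scattering_three_site(m1, 1.0, og)
  expect_equal(s1$elastic_weight, 1.5 * exp(-0.04))
  expect_true(all(s1$quasielastic == 0))
  # symbolic elastic + unit-area Lorentzian: total weight = amplitude * DW
  m2 <- three_site_model(gamma = 0.3, immobile_fraction = 0.4, msd = 0.04)
  s2 <- ideal_scattering_three_site(m2, 1.0, og)
  a0 <- eisf_three_site(1.0, 1.03)
  qe_weight <- (1 - 0.4) * (1 - a0) * exp(-0.04)
  expect_equal(s2$elastic_weight + qe_weight, exp(-0.04))
  # the discrete quasielastic integral matches the analytic on-grid mass
  expect_equal(sum(s2$quasielastic) * diff(og[1:2]),
               qe_weight * 2 / pi * atan(2 / 0.3), tolerance = 1e-3)
  # Q -> 0 with c = 0: all elastic
  s3 <- ideal_scattering_three_site(three_site_model(gamma = 0.3), 1e-9, og)
  expect_equal(sum(s3$quasielastic), 0, tolerance = 1e-12)
})

test_that("log-normal half-width grid has the documented span, symmetry and cutoff", {
  g <- lognormal_gamma_grid(0.2, 0.8, 21L, 0.1)
  expect_length(g$gamma, 21L)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  # half-span in log gamma = s * sqrt(2 ln 10) for cutoff 0.1
  expect_equal(log(max(g$gamma)) - log(0.2), 0.8 * sqrt(2 * log(10)),
               tolerance = 1e-12)
  expect_equal(log(max(g$gamma)) - log(0.2), 0.8 * 2.1460, tolerance = 1e-4)
  # endpoint density / max density = cutoff (before normalization)
  expect_equal(g$weights[1] / max(g$weights), 0.1, tolerance = 1e-12)
  expect_equal(g$weights[21] / max(g$weights), 0.1, tolerance = 1e-12)
  # symmetric about the central component
  expect_equal(g$weights, rev(g$weights), tolerance = 1e-12)
  expect_equal(g$gamma[11], 0.2, tolerance = 1e-12)
  # degenerate grid at s = 0
  g0 <- lognormal_gamma_grid(0.2, 0, 21L, 0.1)
  expect_identical(g0$gamma, 0.2)
  expect_identical(g0$weights, 1)
})

test_that("distribution law equals the single-Gamma law at s = 0 and broadens above", {
  og <- seq(-2, 2, length.out = 801L)
  single <- three_site_model(gamma = 0.2, immobile_fraction = 0.3, msd = 0.02)
  dist0 <- rate_distribution_model(gamma_center = 0.2, sigma_log = 0,
                                   immobile_fraction = 0.3, msd = 0.02)
  i1 <- ideal_scattering_three_site(single, 1.1, og)
  i2 <- ideal_scattering_distribution(dist0, 1.1, og)
  expect_equal(i2$quasielastic, i1$quasielastic, tolerance = 1e-12)
  expect_identical(i2$elastic_weight, i1$elastic_weight)
  # a broad mixture has heavier wings at 10x the center width
  dist1 <- rate_distribution_model(gamma_center = 0.2, sigma_log = 1.0,
                                   immobile_fraction = 0.3, msd = 0.02)
  i3 <- ideal_scattering_distribution(dist1, 1.1, og)
  at_wing <- which.min(abs(og - 2))
  expect_gt(i3$quasielastic[at_wing], i1$quasielastic[at_wing])
  # the mixture's on-grid mass matches the analytic sum of component
  # masses (each Lorentzian keeps 2/pi atan(2/Gamma_j) of its weight on
  # a +/-2 meV grid); the symbolic total weight is s-independent
  g <- lognormal_gamma_grid(0.2, 1.0, 21L, 0.1)
  qe_weight <- (1 - 0.3) * (1 - eisf_three_site(1.1, 1.03)) * exp(-0.02 * 1.1^2)
  expect_equal(sum(i3$quasielastic) * diff(og[1:2]),
               qe_weight * sum(g$weights * 2 / pi * atan(2 / g$gamma)),
               tolerance = 1e-3)
})

test_that("resolution convolution matches the quadrature Voigt oracle", {
  inst <- instrument_config()
  res <- generate_resolution(inst)
  mod <- three_site_model(gamma = 0.6, immobile_fraction = 12 / 18, msd = 0.05)
  ideal <- ideal_scattering_three_site(mod, 1.2, inst$omega_grid)
  meas <- convolve_resolution(ideal, res, inst$omega_grid)
  sigma <- inst$resolution_fwhm / (2 * sqrt(2 * log(2)))
  sel <- abs(inst$omega_grid) <= 1
  a0 <- eisf_three_site(1.2, 1.03)
  dwf <- exp(-0.05 * 1.2^2)
  cim <- 12 / 18
  oracle <- dwf * (cim + (1 - cim) * a0) * dnorm(inst$omega_grid[sel], 0, sigma) +
    dwf * (1 - cim) * (1 - a0) * voigt_quad(inst$omega_grid[sel], sigma, 0.6)
  expect_lt(max(abs(meas[sel] - oracle) / oracle), 1e-3)
})

test_that("convolution preserves the on-grid integral and pure-elastic shape", {
  inst <- instrument_config()
  res <- generate_resolution(inst)
  dw <- diff(inst$omega_grid[1:2])
  mod <- three_site_model(gamma = 0.3, immobile_fraction = 0.5, msd = 0.02)
  ideal <- ideal_scattering_three_site(mod, 0.9, inst$omega_grid)
  meas <- convolve_resolution(ideal, res, inst$omega_grid)
  pre <- ideal$elastic_weight + sum(ideal$quasielastic) * dw
  post <- sum(meas) * dw
  expect_lt(abs(post - pre) / pre, 0.005)
  # zero quasielastic part: output is the scaled resolution
  elastic_only <- list(elastic_weight = 0.7,
                       quasielastic = numeric(length(inst$omega_grid)),
                       omega = inst$omega_grid)
  expect_equal(convolve_resolution(elastic_only, res, inst$omega_grid),
               0.7 * res$values, tolerance = 1e-12)
})

test_that("convolution refuses incompatible grids instead of resampling", {
  inst <- instrument_config()
  res_coarse <- resolution_function(seq(-1, 1, length.out = 201L),
                                    local({
                                      og <- seq(-1, 1, length.out = 201L)
                                      v <- dnorm(og, 0, 0.017)
                                      v / (sum(v) * diff(og[1:2]))
                                    }), fwhm = 0.04)
  mod <- three_site_model(gamma = 0.3)
  ideal <- ideal_scattering_three_site(mod, 1.0, inst$omega_grid)
  expect_error(convolve_resolution(ideal, res_coarse, inst$omega_grid),
               "incompatible grids")
})

test_that("gamma to correlation-time conversion uses tau = hbar/gamma", {
  expect_equal(as.numeric(gamma_to_tau(0.6582119569)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(gamma_to_tau(0.25)), 2 * as.numeric(gamma_to_tau(0.5)))
  expect_equal(as.numeric(gamma_to_tau(0.598)), 1.1, tolerance = 1e-2)
  expect_match(attr(gamma_to_tau(0.1), "convention"), "hbar")
  expect_error(gamma_to_tau(0), "positive")
})

test_that("correlation-time distribution mirrors the rate grid", {
  # mode at 4 ps, support spanning a factor of 10 in tau
  hbar <- reorient_constants()$hbar_meV_ps
  s <- log(10) / (2 * sqrt(2 * log(10)))
  m <- rate_distribution_model(gamma_center = hbar / 4, sigma_log = s)
  td <- tau_distribution(m)
  expect_equal(td$summary$mode, 4, tolerance = 1e-12)
  expect_equal(td$summary$span, c(4 / sqrt(10), 4 * sqrt(10)),
               tolerance = 1e-12)
  expect_equal(sum(td$weights), 1, tolerance = 1e-9)
  # increasing Gamma grid maps to strictly decreasing tau
  expect_true(all(diff(td$tau_values) < 0))
  # span in log tau equals span in log gamma exactly
  g <- lognormal_gamma_grid(m$gamma_center, m$sigma_log, m$n_components,
                            m$cutoff)
  expect_equal(diff(range(log(td$tau_values))), diff(range(log(g$gamma))),
               tolerance = 1e-12)
  # degenerate case
  td0 <- tau_distribution(rate_distribution_model(hbar / 4, 0))
  expect_identical(td0$weights, 1)
  expect_equal(td0$tau_values, 4)
})

test_that("global three-site fit recovers the generating half-width", {
  inst <- make_instrument(6L)
  truth <- three_site_model(gamma = 0.60, immobile_fraction = 12 / 18,
                            msd = 0.05)
  sp <- generate_qens_spectrum(truth, inst, noise_spec(0.02, 5))
  res <- generate_resolution(inst)
  fit <- fit_three_site(sp, res, config = list(n_starts = 3L), seed = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$gamma - 0.60) / 0.60, 0.10)
  expect_lt(abs(fit$model$immobile_fraction - 12 / 18), 0.1)
})

test_that("round trip through the fit reproduces a 1.1 ps correlation time", {
  inst <- make_instrument(4L)
  truth <- three_site_model(gamma = 0.598, immobile_fraction = 12 / 18,
                            msd = 0.05)
  sp <- generate_qens_spectrum(truth, inst, noise_spec(0.02, 9))
  fit <- fit_three_site(sp, generate_resolution(inst),
                        config = list(n_starts = 3L), seed = 2)
  expect_equal(as.numeric(gamma_to_tau(fit$model$gamma)), 1.1,
               tolerance = 0.1)
})

test_that("distribution fit recovers s and gamma_center and beats the nested fit", {
  inst <- make_instrument(6L)
  truth <- rate_distribution_model(gamma_center = 0.16, sigma_log = 1.0,
                                   immobile_fraction = 12 / 18, msd = 0.05)
  sp <- generate_qens_spectrum(truth, inst, noise_spec(0.02, 11))
  res <- generate_resolution(inst)
  fit <- fit_distribution(sp, res, config = list(n_starts = 2L), seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$sigma_log - 1.0), 0.15)
  expect_lt(abs(fit$model$gamma_center - 0.16) / 0.16, 0.10)
  expect_gt(fit$single_gamma_fit$residual_norm, fit$residual_norm)
})

test_that("distribution fit at the s = 0 boundary stays consistent with zero", {
  inst <- make_instrument(4L)
  truth <- rate_distribution_model(gamma_center = 0.3, sigma_log = 0,
                                   immobile_fraction = 0.5, msd = 0.02)
  sp <- generate_qens_spectrum(truth, inst, noise_spec(0.02, 21))
  res <- generate_resolution(inst)
  fit <- fit_distribution(sp, res, config = list(n_starts = 2L), seed = 4)
  s_hat <- fit$model$sigma_log
  s_se <- if (!is.null(fit$parameter_uncertainties))
    fit$parameter_uncertainties[2L] else NA_real_
  tol <- if (is.finite(s_se) && s_se > 0) 2 * s_se else 0.15
  expect_lt(s_hat, max(tol, 0.15))
})
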