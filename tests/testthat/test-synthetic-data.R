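test_that("generators are deterministic under a fixed seed", {
  p <- arrhenius_process(2e-12, 7.8, 2.2e9)
  temps <- seq(50, 300, length.out = 30)
  c1 <- generate_t1_curve(list(p), 25, temps, noise_spec(0.02, 99))
  c2 <- generate_t1_curve(list(p), 25, temps, noise_spec(0.02, 99))
  expect_identical(c1$t1_values, c2$t1_values)
  c3 <- generate_t1_curve(list(p), 25, temps, noise_spec(0.02, 100))
  expect_false(identical(c1$t1_values, c3$t1_values))

  d <- recovery_delay_grid(0.2, 2.0)
  t1 <- generate_recovery_trace(rbind(c(0.5, 0.2), c(0.5, 2)), d,
                                noise_spec(0.01, 7))
  t2 <- generate_recovery_trace(rbind(c(0.5, 0.2), c(0.5, 2)), d,
                                noise_spec(0.01, 7))
  expect_identical(t1$magnetization, t2$magnetization)

  inst <- make_instrument(2L)
  mod <- three_site_model(gamma = 0.3, immobile_fraction = 0.5)
  s1 <- generate_qens_spectrum(mod, inst, noise_spec(0.02, 5))
  s2 <- generate_qens_spectrum(mod, inst, noise_spec(0.02, 5))
  expect_identical(s1[[1]]$intensity, s2[[1]]$intensity)
  expect_identical(s1[[2]]$intensity, s2[[2]]$intensity)
})

test_that("noiseless T1 curves satisfy the BPP model pointwise", {
  m <- amorphous_t1_scenario()
  temps <- seq(30, 290, length.out = 40)
  curve <- generate_t1_curve(m$processes, 25, temps, noise_spec(0, 1))
  expect_equal(curve$t1_values, 1 / model_rate(m, temps), tolerance = 1e-12)
  expect_null(curve$t1_uncertainties)
  # noisy curve stores relative uncertainties
  noisy <- generate_t1_curve(m$processes, 25, temps, noise_spec(0.02, 1))
  expect_equal(noisy$t1_uncertainties, 0.02 * noisy$t1_values)
})

test_that("noiseless single-process curve minimum sits at the BPP condition", {
  p <- arrhenius_process(2e-12, 7.8, 2.2e9)
  temps <- seq(80, 280, length.out = 4000)
  curve <- generate_t1_curve(list(p), 25, temps, noise_spec(0, 1))
  T_min <- curve$temperatures[which.min(curve$t1_values)]
  x_at_min <- 2 * pi * 25e6 * arrhenius_tau(p, T_min)
  expect_equal(x_at_min, 0.6158, tolerance = 1e-3)
})

test_that("six-process curve with the tabulated amorphous barriers has two minima", {
  ea <- c(7.8, 6.8, 5.4, 4.4, 3.7, 3.0)
  m <- amorphous_t1_scenario()
  got <- sort(vapply(m$processes, function(p) p$activation_energy,
                     numeric(1L)), decreasing = TRUE)
  expect_equal(got, ea)
  temps <- seq(20, 300, length.out = 500)
  curve <- generate_t1_curve(m$processes, 25, temps, noise_spec(0, 1))
  lt1 <- log(curve$t1_values)
  mins <- which(c(FALSE, diff(sign(diff(lt1))) > 0, FALSE))
  expect_gte(length(mins), 2L)
})

test_that("recovery traces follow the multi-exponential closed form", {
  # single component at delay = T1: Mz = M0 (1 - 1/e)
  tr <- generate_recovery_trace(rbind(c(2, 0.5)), c(0, 0.25, 0.5, 1, 2, 5),
                                noise_spec(0, 1))
  expect_equal(tr$magnetization[tr$delays == 0.5], 2 * (1 - exp(-1)))
  expect_identical(tr$magnetization[1], 0)
  # all-zero delays give all-zero magnetization
  tr0 <- generate_recovery_trace(rbind(c(1, 0.5)), rep(0, 6), noise_spec(0, 1))
  expect_identical(tr0$magnetization, rep(0, 6))
  # two components sum
  d <- c(0.1, 0.5, 1, 3)
  tr2 <- generate_recovery_trace(rbind(c(0.4, 0.2), c(0.6, 2)), d,
                                 noise_spec(0, 1))
  expect_equal(tr2$magnetization,
               0.4 * (1 - exp(-d / 0.2)) + 0.6 * (1 - exp(-d / 2)))
  expect_error(generate_recovery_trace(rbind(c(0, 1)), d, noise_spec(0, 1)),
               "degenerate")
})

test_that("recrystallization series reproduces the requested fractions", {
  traj <- data.frame(time = c(0, 50, 105), fraction = c(0, 0.5, 1))
  traces <- generate_recrystallization_series(traj, noise = noise_spec(0, 1))
  expect_length(traces, 3L)
  expect_equal(vapply(traces, function(tr) tr$timestamp, numeric(1L)),
               traj$time)
  # final trace is purely mono-exponential with the crystalline T1
  gt <- traces[[3]]$metadata$ground_truth
  expect_equal(gt$crystalline_fraction, 1)
  expect_length(gt$amplitudes, 1L)
  expect_equal(gt$t1, 2.0)
  # constant-zero trajectory gives amorphous mono traces
  traj0 <- data.frame(time = c(1, 2), fraction = c(0, 0))
  tr0 <- generate_recrystallization_series(traj0, noise = noise_spec(0, 1))
  expect_equal(tr0[[1]]$metadata$ground_truth$t1, 0.2)
  expect_error(generate_recrystallization_series(
    data.frame(time = 1, fraction = 1.2)), "\\[0, 1\\]")
})

test_that("resolution generator produces a unit-area Gaussian of the set FWHM", {
  inst <- instrument_config(resolution_fwhm = 0.04)
  res <- generate_resolution(inst)
  dw <- diff(res$omega[1:2])
  expect_equal(sum(res$values) * dw, 1, tolerance = 1e-6)
  # closed-form peak height 2 sqrt(ln 2 / pi) / FWHM
  expect_equal(max(res$values), 2 * sqrt(log(2) / pi) / 0.04,
               tolerance = 1e-9)
  # the line shape reaches half its maximum exactly FWHM apart
  at_half <- stats::approx(res$omega, res$values, xout = c(-0.02, 0.02))$y
  expect_equal(at_half, rep(max(res$values) / 2, 2L), tolerance = 1e-4)
})

test_that("QENS generator refuses an omega grid that would truncate the resolution", {
  inst_bad <- instrument_config(omega_grid = seq(-0.3, 0.3, length.out = 121L),
                                resolution_fwhm = 0.04)
  mod <- three_site_model(gamma = 0.1)
  expect_error(generate_qens_spectrum(mod, inst_bad), "too narrow")
})

test_that("gamma -> 0 spectra collapse to the scaled resolution line shape", {
  inst <- make_instrument(1L)
  mod <- three_site_model(gamma = 0, immobile_fraction = 0.3, msd = 0.02,
                          amplitude = 2)
  sp <- generate_qens_spectrum(mod, inst, noise_spec(0, 1))[[1]]
  res <- generate_resolution(inst)
  expect_equal(sp$intensity, 2 * exp(-0.02 * sp$q^2) * res$values,
               tolerance = 1e-12)
})

test_that("noiseless single-Gamma spectra match the quadrature Voigt oracle", {
  inst <- make_instrument(1L)
  mod <- three_site_model(gamma = 0.6, immobile_fraction = 12 / 18, msd = 0.05)
  sp <- generate_qens_spectrum(mod, inst, noise_spec(0, 1))[[1]]
  sigma <- inst$resolution_fwhm / (2 * sqrt(2 * log(2)))
  a0 <- eisf_three_site(sp$q, mod$radius)
  dwf <- exp(-mod$msd * sp$q^2)
  cim <- mod$immobile_fraction
  sel <- abs(sp$omega) <= 1
  oracle <- dwf * (cim + (1 - cim) * a0) * dnorm(sp$omega[sel], 0, sigma) +
    dwf * (1 - cim) * (1 - a0) * voigt_quad(sp$omega[sel], sigma, mod$gamma)
  expect_lt(max(abs(sp$intensity[sel] - oracle) / oracle), 1e-6)
})

test_that("distribution generator with s = 0 reproduces the single-Gamma spectra", {
  inst <- make_instrument(2L)
  single <- three_site_model(gamma = 0.25, immobile_fraction = 0.4, msd = 0.03)
  dist <- rate_distribution_model(gamma_center = 0.25, sigma_log = 0,
                                  immobile_fraction = 0.4, msd = 0.03)
  s1 <- generate_qens_spectrum(single, inst, noise_spec(0, 1))
  s2 <- generate_qens_spectrum(dist, inst, noise_spec(0, 1))
  for (i in seq_along(s1)) {
    expect_equal(s1[[i]]$intensity, s2[[i]]$intensity, tolerance = 1e-12)
  }
})

test_that("generated data carry their ground truth in metadata", {
  p <- arrhenius_process(2e-12, 7.8, 2.2e9)
  curve <- generate_t1_curve(list(p), 25, seq(50, 250, length.out = 10),
                             noise_spec(0.02, 3))
  expect_equal(curve$metadata$ground_truth[[1]]$activation_energy, 7.8)
  expect_equal(curve$metadata$seed, 3L)
  tr <- generate_recovery_trace(rbind(c(1, 0.5)), recovery_delay_grid(0.5, 0.5),
                                noise_spec(0.01, 4))
  expect_equal(tr$metadata$ground_truth$t1, 0.5)
})
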