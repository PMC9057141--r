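test_that("mono-exponential fit recovers noiseless parameters and scales with Mz", {
  tr <- generate_recovery_trace(rbind(c(1.7, 0.45)),
                                recovery_delay_grid(0.45, 0.45),
                                noise_spec(0, 1))
  fit <- fit_mono(tr)
  expect_true(fit$converged)
  expect_equal(fit$m0, 1.7, tolerance = 1e-8)
  expect_equal(fit$t1, 0.45, tolerance = 1e-8)
  # doubling Mz doubles m0, leaves t1 unchanged
  tr2 <- recovery_trace(tr$delays, 2 * tr$magnetization)
  fit2 <- fit_mono(tr2)
  expect_equal(fit2$m0, 2 * fit$m0, tolerance = 1e-8)
  expect_equal(fit2$t1, fit$t1, tolerance = 1e-6)
})

test_that("a saturated trace is flagged rather than fitted", {
  tr <- recovery_trace(recovery_delay_grid(0.5, 0.5),
                       rep(1, 12) + 1e-4 * sin(1:12))
  fit <- fit_mono(tr)
  expect_false(fit$converged)
  expect_match(fit$flags, "no decay information", all = FALSE)
})

test_that("bi-exponential fit recovers a 50/50 mixture with T1 ratio 10", {
  passes <- 0L
  for (s in 1:10) {
    tr <- generate_recovery_trace(rbind(c(0.5, 0.2), c(0.5, 2.0)),
                                  recovery_delay_grid(0.2, 2.0, 12),
                                  noise_spec(0.01, s))
    fit <- fit_biexp(tr, seed = s)
    expect_lt(fit$t1_1, fit$t1_2)  # canonical ordering
    f <- crystalline_fraction(fit)$crystalline_fraction
    if (abs(f - 0.5) <= 0.03) passes <- passes + 1L
  }
  expect_gte(passes, 9L)
})

test_that("bi-exponential fit flags near-degenerate components on mono data", {
  tr <- generate_recovery_trace(rbind(c(1, 0.5)),
                                recovery_delay_grid(0.5, 0.5, 12),
                                noise_spec(0.01, 2))
  fit <- fit_biexp(tr, seed = 1)
  small_amp <- min(fit$m0_1, fit$m0_2) / (fit$m0_1 + fit$m0_2) < 0.05
  degenerate <- length(fit$warnings) > 0
  expect_true(small_amp || degenerate)
})

test_that("model selection prefers the true shape and keeps parsimony on ties", {
  # strongly bi-exponential data
  tr_bi <- generate_recovery_trace(rbind(c(0.5, 0.2), c(0.5, 2.0)),
                                   recovery_delay_grid(0.2, 2.0, 12),
                                   noise_spec(0.01, 3))
  expect_identical(select_model(tr_bi, "f_test", seed = 1)$selected, "biexp")
  expect_identical(select_model(tr_bi, "aic", seed = 1)$selected, "biexp")
  # mono data: selected mono in >= 90% of seeded replicates
  n_mono <- 0L
  for (r in 1:100) {
    tr <- generate_recovery_trace(rbind(c(1, 0.5)),
                                  recovery_delay_grid(0.5, 0.5, 12),
                                  noise_spec(0.01, 300 + r))
    sel <- select_model(tr, "f_test", seed = r)
    if (sel$selected == "mono") n_mono <- n_mono + 1L
  }
  expect_gte(n_mono, 90L)
})

test_that("phase fractions are exact amplitude shares", {
  mk <- function(m1, m2) structure(
    list(m0_1 = m1, m0_2 = m2, t1_1 = 0.2, t1_2 = 2, uncertainties = NULL,
         residual_norm = 0, converged = TRUE, warnings = character()),
    class = "biexp_fit")
  expect_equal(crystalline_fraction(mk(1, 1))$crystalline_fraction, 0.5)
  expect_equal(crystalline_fraction(mk(1, 0))$crystalline_fraction, 0)
  expect_equal(crystalline_fraction(mk(1, 3))$crystalline_fraction, 0.75)
  expect_equal(crystalline_fraction(mk(1, 3),
                                    "shorter_is_crystalline")$crystalline_fraction,
               0.25)
  # complementary assignments sum to one exactly
  f1 <- crystalline_fraction(mk(0.3, 1.2))$crystalline_fraction
  f2 <- crystalline_fraction(mk(0.3, 1.2),
                             "shorter_is_crystalline")$crystalline_fraction
  expect_equal(f1 + f2, 1, tolerance = 1e-15)
  expect_error(crystalline_fraction(mk(0, 0)), "zero total")
})

test_that("kinetics round trip recovers the completion day", {
  times <- seq(7, 126, by = 7)
  traj <- logistic_trajectory(times)  # reaches 0.99 at day 105
  traces <- generate_recrystallization_series(traj, noise = noise_spec(0.01, 42))
  kin <- build_kinetics(traces, config = list(t1_amorphous = 0.2,
                                              t1_crystalline = 2.0))
  expect_true(kin$completion_reached)
  expect_lte(abs(kin$completion_time - 105), 7)
  expect_true(all(kin$points$crystalline_fraction >= 0 &
                    kin$points$crystalline_fraction <= 1))
})

test_that("kinetics reports non-completion for a persistently amorphous series", {
  traj <- data.frame(time = c(7, 14, 21), fraction = c(0, 0, 0))
  traces <- generate_recrystallization_series(traj, noise = noise_spec(0.005, 8))
  kin <- build_kinetics(traces, config = list(t1_amorphous = 0.2,
                                              t1_crystalline = 2.0))
  expect_false(kin$completion_reached)
  expect_true(is.na(kin$completion_time))
  expect_true(all(kin$points$crystalline_fraction < 0.5))
})

test_that("unordered timestamps are sorted with a warning entry", {
  traj <- data.frame(time = c(7, 50, 105), fraction = c(0, 0.5, 1))
  traces <- generate_recrystallization_series(traj, noise = noise_spec(0.01, 4))
  kin <- build_kinetics(rev(traces), config = list(t1_amorphous = 0.2,
                                                   t1_crystalline = 2.0))
  expect_match(kin$warnings, "unordered", all = FALSE)
  expect_equal(kin$points$time, traj$time)
})

test_that("fractions track a monotone trajectory within noise", {
  times <- seq(14, 112, by = 14)
  traj <- logistic_trajectory(times)
  traces <- generate_recrystallization_series(traj, noise = noise_spec(0.01, 17))
  kin <- build_kinetics(traces, config = list(t1_amorphous = 0.2,
                                              t1_crystalline = 2.0))
  expect_lt(max(abs(kin$points$crystalline_fraction - traj$fraction)), 0.1)
})
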