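#' Six-process amorphous relaxation scenario
#'
#' The packaged ground-truth model for an amorphous dihydropyridine-type
#' solid: one high-temperature BPP process (the ethyl-ester methyl) with
#' EA = 7.8 kJ/mol and five low-temperature processes (the ring-side
#' methyls seen through a barrier distribution) with EA = 6.8, 5.4,
#' 4.4, 3.7 and 3.0 kJ/mol. tau0 values are chosen so the two T1 minima
#' fall near 142 K and 63 K at 25 MHz, and strengths so the minima sit
#' at tens of milliseconds — representative magnitudes for proton
#' relaxometry of methyl-bearing organics.
#'
#' @param larmor_frequency MHz (default 25).
#' @return A [relaxation_model()].
#' @export
amorphous_t1_scenario <- function(larmor_frequency = 25.0) {
  omega0 <- 2 * pi * larmor_frequency * 1e6
  x_star <- t1_minimum_condition()$x_star
  tau_min <- x_star / omega0
  tau0_for <- function(ea_kj, T_min) tau_min * exp(-ea_kj * 1000 / (.R_GAS * T_min))
  ea_high <- 7.8
  ea_low <- c(6.8, 5.4, 4.4, 3.7, 3.0)
  procs <- c(
    list(arrhenius_process(tau0_for(ea_high, 142), ea_high, 2.2e9,
                           label = "methyl IV (high-T)")),
    lapply(seq_along(ea_low), function(i) {
      arrhenius_process(tau0_for(4.4, 63), ea_low[i], 4.5e8,
                        label = sprintf("methyl I-III component %d", i))
    }))
  relaxation_model(procs, larmor_frequency)
}

#' Generate a noisy T1 relaxation curve
#'
#' Evaluates the summed BPP rate of the given processes at each
#' temperature, inverts to T1, and applies multiplicative Gaussian
#' noise: T1_obs = T1 (1 + eps), eps ~ N(0, relative_sd). Stored
#' uncertainties are relative_sd * T1_obs.
#'
#' @param processes List of [arrhenius_process()] objects (non-empty).
#' @param larmor_frequency MHz.
#' @param temperatures Temperatures (K), all > 0.
#' @param noise A [noise_spec()].
#' @return A [relaxation_curve()] whose metadata records the ground
#'   truth parameters, frequency and noise spec.
#' @export
generate_t1_curve <- function(processes, larmor_frequency, temperatures,
                              noise = noise_spec()) {
  model <- relaxation_model(processes, larmor_frequency)  # validates
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_domain("all temperatures must be positive (K)")
  stopifnot(inherits(noise, "noise_spec"))
  t1 <- 1 / model_rate(model, temperatures)
  t1_obs <- if (noise$relative_sd > 0) {
    with_seed(noise$seed,
              t1 * (1 + stats::rnorm(length(t1), 0, noise$relative_sd)))
  } else t1
  if (any(t1_obs <= 0))
    stop_domain("noise level produced non-positive T1; reduce 'relative_sd'")
  relaxation_curve(
    temperatures, t1_obs,
    t1_uncertainties = if (noise$relative_sd > 0) noise$relative_sd * t1_obs else NULL,
    metadata = list(
      ground_truth = lapply(model$processes, unclass),
      larmor_frequency = larmor_frequency,
      relative_sd = noise$relative_sd, seed = noise$seed))
}

#' Generate a saturation-recovery trace
#'
#' Mz(tau) = sum_k M0_k (1 - exp(-tau / T1_k)) plus additive Gaussian
#' noise of standard deviation relative_sd * sum(M0) (noise scaled to
#' the equilibrium magnetization, as for a fixed receiver gain).
#'
#' @param fractions Two-column matrix or list of c(amplitude, T1)
#'   pairs; amplitudes >= 0 with at least one > 0, T1 > 0.
#' @param delays Delays (s), >= 0.
#' @param noise A [noise_spec()].
#' @param timestamp Days since amorphization recorded on the trace.
#' @return A [recovery_trace()] with ground truth in metadata.
#' @export
generate_recovery_trace <- function(fractions, delays, noise = noise_spec(),
                                    timestamp = NA_real_) {
  if (is.list(fractions)) fractions <- do.call(rbind, fractions)
  fractions <- matrix(as.numeric(fractions), ncol = 2L)
  amp <- fractions[, 1L]; t1 <- fractions[, 2L]
  if (any(!is.finite(amp)) || any(amp < 0))
    stop_domain("amplitudes must be non-negative")
  if (all(amp == 0))
    stop_domain("degenerate trace: all amplitudes are zero")
  if (any(!is.finite(t1)) || any(t1 <= 0))
    stop_domain("all T1 values must be positive (s)")
  delays <- as.numeric(delays)
  if (any(!is.finite(delays)) || any(delays < 0))
    stop_domain("delays must be non-negative (s)")
  stopifnot(inherits(noise, "noise_spec"))
  mz <- rowSums(vapply(seq_along(amp), function(k) {
    amp[k] * (1 - exp(-delays / t1[k]))
  }, numeric(length(delays))))
  sd_abs <- noise$relative_sd * sum(amp)
  mz_obs <- if (sd_abs > 0) {
    with_seed(noise$seed, mz + stats::rnorm(length(mz), 0, sd_abs))
  } else mz
  recovery_trace(
    delays, mz_obs,
    uncertainties = if (sd_abs > 0) rep(sd_abs, length(delays)) else NULL,
    timestamp = timestamp,
    metadata = list(ground_truth = list(amplitudes = amp, t1 = t1),
                    relative_sd = noise$relative_sd, seed = noise$seed))
}

#' Log-spaced delay grid for synthetic recovery traces
#'
#' @param t1_short,t1_long Component relaxation times (s).
#' @param n Number of delays.
#' @return Delays log-spaced over [t1_short / 10, 5 t1_long].
#' @export
recovery_delay_grid <- function(t1_short, t1_long, n = 12L) {
  exp(seq(log(t1_short / 10), log(5 * t1_long), length.out = as.integer(n)))
}

#' Logistic recrystallization trajectory
#'
#' Convenience parameterization of a crystalline-fraction time course,
#' f(t) = 1 / (1 + exp(-rate (t - midpoint))). A stand-in for the
#' unknown true kinetic law; any tabulated trajectory can be supplied
#' to [generate_recrystallization_series()] instead. The defaults
#' reach f = 0.99 at day 105 (midpoint 60 days).
#'
#' @param times Times in days.
#' @param midpoint Day at which f = 0.5.
#' @param rate Logistic rate (1/days).
#' @return data.frame with columns `time`, `fraction`.
#' @export
logistic_trajectory <- function(times, midpoint = 60,
                                rate = log(99) / 45) {
  data.frame(time = as.numeric(times),
             fraction = 1 / (1 + exp(-rate * (as.numeric(times) - midpoint))))
}

#' Generate a recrystallization series of recovery traces
#'
#' One bi-exponential recovery trace per trajectory point: the
#' crystalline fraction f sets the amplitude split
#' (M0 (1 - f), T1_amorphous) + (M0 f, T1_crystalline). Each trace
#' carries its timestamp and the full ground truth in metadata. A
#' fresh sub-seed per time point keeps traces independent yet
#' reproducible.
#'
#' @param trajectory data.frame with columns `time` (days,
#'   non-decreasing) and `fraction` (in [0, 1]).
#' @param t1_amorphous,t1_crystalline Phase relaxation times (s).
#' @param m0_total Total equilibrium magnetization.
#' @param delays Delay grid (s); default [recovery_delay_grid()] over
#'   the two T1 values.
#' @param noise A [noise_spec()].
#' @return List of [recovery_trace()] objects.
#' @export
generate_recrystallization_series <- function(trajectory,
                                              t1_amorphous = 0.2,
                                              t1_crystalline = 2.0,
                                              m0_total = 1.0,
                                              delays = NULL,
                                              noise = noise_spec()) {
  stopifnot(is.data.frame(trajectory),
            all(c("time", "fraction") %in% names(trajectory)))
  f <- trajectory$fraction; tm <- trajectory$time
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop_domain("trajectory fractions must lie in [0, 1]")
  if (is.unsorted(tm))
    stop_domain("trajectory times must be non-decreasing")
  if (is.null(delays))
    delays <- recovery_delay_grid(min(t1_amorphous, t1_crystalline),
                                  max(t1_amorphous, t1_crystalline))
  lapply(seq_along(tm), function(i) {
    comps <- rbind(c(m0_total * (1 - f[i]), t1_amorphous),
                   c(m0_total * f[i], t1_crystalline))
    comps <- comps[comps[, 1L] > 0, , drop = FALSE]
    if (nrow(comps) == 0L) comps <- rbind(c(m0_total, t1_amorphous))
    tr <- generate_recovery_trace(
      comps, delays,
      noise = noise_spec(noise$relative_sd, noise$seed + i),
      timestamp = tm[i])
    tr$metadata$ground_truth$crystalline_fraction <- f[i]
    tr$metadata$ground_truth$t1_amorphous <- t1_amorphous
    tr$metadata$ground_truth$t1_crystalline <- t1_crystalline
    tr
  })
}

#' Generate the instrument resolution function
#'
#' Unit-area Gaussian on the instrument's energy grid with the
#' configured FWHM — the synthetic counterpart of a vanadium
#' elastic-standard measurement.
#'
#' @param instrument An [instrument_config()].
#' @return A [resolution_function()].
#' @export
generate_resolution <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_config"))
  sigma <- instrument$resolution_fwhm / (2 * sqrt(2 * log(2)))
  vals <- stats::dnorm(instrument$omega_grid, 0, sigma)
  resolution_function(instrument$omega_grid, vals,
                      fwhm = instrument$resolution_fwhm)
}

#' Generate QENS spectra from a jump model
#'
#' For each configured momentum transfer, evaluates the ideal
#' scattering law (single-Gamma three-site or rate-distribution),
#' convolves it with the Gaussian instrument resolution, and applies
#' multiplicative Gaussian noise. Uncertainties are
#' relative_sd * intensity floored at 5% of the spectrum maximum times
#' relative_sd (a counting-statistics-like floor that keeps weights
#' finite near zero intensity).
#'
#' @param model A [three_site_model()] or [rate_distribution_model()].
#' @param instrument An [instrument_config()] whose grid spans at
#'   least +/- 10 resolution FWHM (refused otherwise rather than
#'   silently clipped).
#' @param noise A [noise_spec()].
#' @return List of [qens_spectrum()] objects, one per Q, each with the
#'   resolution attached and ground truth in metadata.
#' @export
generate_qens_spectrum <- function(model, instrument, noise = noise_spec()) {
  stopifnot(inherits(instrument, "instrument_config"),
            inherits(noise, "noise_spec"))
  if (!(inherits(model, "three_site_model") ||
        inherits(model, "rate_distribution_model")))
    stop_domain("'model' must be a three_site_model or rate_distribution_model")
  og <- instrument$omega_grid
  span <- min(abs(min(og)), abs(max(og)))
  if (span < 10 * instrument$resolution_fwhm)
    stop_domain("omega_grid too narrow: must span at least +/-10 resolution FWHM")
  res <- generate_resolution(instrument)
  lapply(seq_along(instrument$q_values), function(i) {
    q <- instrument$q_values[i]
    ideal <- if (inherits(model, "rate_distribution_model")) {
      ideal_scattering_distribution(model, q, og)
    } else {
      ideal_scattering_three_site(model, q, og)
    }
    s <- convolve_resolution(ideal, res, og)
    if (noise$relative_sd > 0) {
      s_obs <- with_seed(noise$seed + i,
                         s * (1 + stats::rnorm(length(s), 0, noise$relative_sd)))
      unc <- pmax(noise$relative_sd * abs(s_obs),
                  noise$relative_sd * max(s) * 0.05)
    } else {
      s_obs <- s
      unc <- NULL
    }
    qens_spectrum(q, og, s_obs, uncertainty = unc, resolution = res,
                  metadata = list(ground_truth = unclass(model),
                                  model_class = class(model),
                                  relative_sd = noise$relative_sd,
                                  seed = noise$seed + i))
  })
}
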