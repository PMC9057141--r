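#' Thermally activated reorientation process
#'
#' Bundles the three parameters of one Arrhenius-activated relaxation
#' channel: the pre-exponential correlation time tau0, the activation
#' energy EA, and the BPP relaxation constant C. C absorbs all dipolar
#' prefactors; no decomposition into second moments is attempted.
#'
#' @param tau0 Pre-exponential correlation time (s), > 0.
#' @param activation_energy Activation energy EA (kJ mol^-1), >= 0.
#' @param strength BPP relaxation constant C (s^-2), > 0.
#' @param label Free-text label, e.g. "methyl IV".
#' @return An object of class `arrhenius_process`.
#' @examples
#' arrhenius_process(1e-13, 13.76, 2e9, label = "methyl IV")
#' @export
arrhenius_process <- function(tau0, activation_energy, strength, label = "") {
  if (!is.numeric(tau0) || length(tau0) != 1L || !is.finite(tau0) || tau0 <= 0)
    stop_domain("'tau0' must be a single positive number (seconds)")
  if (!is.numeric(activation_energy) || length(activation_energy) != 1L ||
      !is.finite(activation_energy) || activation_energy < 0)
    stop_domain("'activation_energy' must be a single non-negative number (kJ/mol)")
  if (!is.numeric(strength) || length(strength) != 1L ||
      !is.finite(strength) || strength <= 0)
    stop_domain("'strength' must be a single positive number (s^-2)")
  structure(
    list(tau0 = tau0, activation_energy = activation_energy,
         strength = strength, label = as.character(label)[1L]),
    class = "arrhenius_process")
}

#' @export
print.arrhenius_process <- function(x, ...) {
  cat(sprintf("Arrhenius process%s: tau0 = %.3g s, EA = %.3g kJ/mol, C = %.3g s^-2\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$tau0, x$activation_energy, x$strength))
  invisible(x)
}

#' Multi-process BPP relaxation model
#'
#' A set of [arrhenius_process()] components observed at a common
#' proton Larmor frequency. The total relaxation rate is the sum of
#' the per-process BPP rates (rates, not times, are additive).
#'
#' @param processes List of `arrhenius_process` objects (at least one).
#' @param larmor_frequency Proton resonance frequency (MHz), > 0.
#' @return An object of class `relaxation_model`.
#' @export
relaxation_model <- function(processes, larmor_frequency) {
  if (inherits(processes, "arrhenius_process")) processes <- list(processes)
  if (!is.list(processes) || length(processes) == 0L)
    stop_domain("'processes' must be a non-empty list of arrhenius_process objects")
  ok <- vapply(processes, inherits, logical(1L), what = "arrhenius_process")
  if (!all(ok))
    stop_domain("all elements of 'processes' must be arrhenius_process objects")
  if (!is.numeric(larmor_frequency) || length(larmor_frequency) != 1L ||
      !is.finite(larmor_frequency) || larmor_frequency <= 0)
    stop_domain("'larmor_frequency' must be a single positive number (MHz)")
  structure(list(processes = processes, larmor_frequency = larmor_frequency),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat(sprintf("BPP relaxation model: %d process(es) at %.3f MHz\n",
              length(x$processes), x$larmor_frequency))
  for (p in x$processes) print(p)
  invisible(x)
}

#' T1 relaxation curve
#'
#' A temperature series of spin-lattice relaxation times, optionally
#' with 1-sigma uncertainties. Stored sorted by increasing temperature.
#'
#' @param temperatures Temperatures (K), all > 0.
#' @param t1_values Relaxation times T1 (s), all > 0, same length.
#' @param t1_uncertainties Optional 1-sigma uncertainties (s).
#' @param metadata Named list of provenance information.
#' @return An object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(temperatures, t1_values, t1_uncertainties = NULL,
                             metadata = list()) {
  temperatures <- as.numeric(temperatures)
  t1_values <- as.numeric(t1_values)
  if (length(temperatures) != length(t1_values))
    stop_domain("'temperatures' and 't1_values' must have equal length")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_domain("all temperatures must be positive and finite (K)")
  if (any(!is.finite(t1_values)) || any(t1_values <= 0))
    stop_domain("all T1 values must be positive and finite (s)")
  if (!is.null(t1_uncertainties)) {
    t1_uncertainties <- as.numeric(t1_uncertainties)
    if (length(t1_uncertainties) != length(t1_values))
      stop_domain("'t1_uncertainties' must match 't1_values' in length")
    if (any(!is.finite(t1_uncertainties)) || any(t1_uncertainties < 0))
      stop_domain("uncertainties must be non-negative and finite")
  }
  ord <- order(temperatures)
  structure(
    list(temperatures = temperatures[ord], t1_values = t1_values[ord],
         t1_uncertainties = if (is.null(t1_uncertainties)) NULL else t1_uncertainties[ord],
         metadata = metadata),
    class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("T1 relaxation curve: %d points, %.1f-%.1f K, T1 %.3g-%.3g s\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              min(x$t1_values), max(x$t1_values)))
  invisible(x)
}

#' Saturation-recovery trace
#'
#' Magnetization Mz versus delay after a saturating pulse train.
#' Delays must be non-negative and non-decreasing; the fitting
#' operations additionally require at least 6 strictly increasing
#' delays.
#'
#' @param delays Recovery delays (s), non-negative, non-decreasing.
#' @param magnetization Mz values (arbitrary units), same length.
#' @param uncertainties Optional 1-sigma uncertainties.
#' @param timestamp Days since amorphization (optional, NA if unknown).
#' @param metadata Named list of provenance information.
#' @return An object of class `recovery_trace`.
#' @export
recovery_trace <- function(delays, magnetization, uncertainties = NULL,
                           timestamp = NA_real_, metadata = list()) {
  delays <- as.numeric(delays)
  magnetization <- as.numeric(magnetization)
  if (length(delays) != length(magnetization))
    stop_domain("'delays' and 'magnetization' must have equal length")
  if (any(!is.finite(delays)) || any(delays < 0))
    stop_domain("delays must be non-negative and finite (s)")
  if (is.unsorted(delays))
    stop_domain("delays must be non-decreasing")
  if (!is.null(uncertainties)) {
    uncertainties <- as.numeric(uncertainties)
    if (length(uncertainties) != length(delays))
      stop_domain("'uncertainties' must match 'delays' in length")
  }
  structure(
    list(delays = delays, magnetization = magnetization,
         uncertainties = uncertainties, timestamp = as.numeric(timestamp)[1L],
         metadata = metadata),
    class = "recovery_trace")
}

#' @export
print.recovery_trace <- function(x, ...) {
  cat(sprintf("Saturation-recovery trace: %d delays, %.3g-%.3g s%s\n",
              length(x$delays), min(x$delays), max(x$delays),
              if (is.finite(x$timestamp)) sprintf(", day %.1f", x$timestamp) else ""))
  invisible(x)
}

#' Spectrometer configuration for synthetic QENS and NMR data
#'
#' Defaults mirror a cold-neutron time-of-flight spectrometer with
#' ~0.04 meV (FWHM) Gaussian energy resolution and a 0.3-1.8 A^-1
#' momentum-transfer range, paired with a 25 MHz proton relaxometer.
#' The default energy grid (-2 to 2 meV, 801 points) accommodates
#' quasielastic half-widths up to ~0.6 meV with adequate wings.
#'
#' @param omega_grid Energy-transfer grid (meV), strictly increasing,
#'   uniformly spaced.
#' @param q_values Momentum transfers (A^-1), all > 0.
#' @param resolution_fwhm Gaussian resolution FWHM (meV), > 0.
#' @param larmor_frequency Proton resonance frequency (MHz), > 0.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(omega_grid = seq(-2, 2, length.out = 801L),
                              q_values = seq(0.3, 1.8, by = 0.3),
                              resolution_fwhm = 0.04,
                              larmor_frequency = 25.0) {
  omega_grid <- as.numeric(omega_grid)
  if (length(omega_grid) < 3L || any(!is.finite(omega_grid)))
    stop_domain("'omega_grid' must be a finite numeric grid of length >= 3")
  d <- diff(omega_grid)
  if (any(d <= 0))
    stop_domain("'omega_grid' must be strictly increasing")
  if (max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop_domain("'omega_grid' must be uniformly spaced")
  q_values <- as.numeric(q_values)
  if (any(!is.finite(q_values)) || any(q_values <= 0))
    stop_domain("all 'q_values' must be positive (A^-1)")
  if (!is.numeric(resolution_fwhm) || resolution_fwhm <= 0)
    stop_domain("'resolution_fwhm' must be positive (meV)")
  if (!is.numeric(larmor_frequency) || larmor_frequency <= 0)
    stop_domain("'larmor_frequency' must be positive (MHz)")
  structure(
    list(omega_grid = omega_grid, q_values = q_values,
         resolution_fwhm = resolution_fwhm,
         larmor_frequency = larmor_frequency),
    class = "instrument_config")
}

#' Noise specification for synthetic data
#'
#' @param relative_sd Fractional Gaussian noise level (>= 0). 0 gives
#'   noiseless data.
#' @param seed Integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0, seed = 1L) {
  if (!is.numeric(relative_sd) || length(relative_sd) != 1L || relative_sd < 0)
    stop_domain("'relative_sd' must be a single non-negative number")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("'seed' must be a single integer")
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Three-site jump scattering model
#'
#' Methyl-type reorientation: hydrogens jump between three equidistant
#' sites on a circle of radius r. The scattering law is an elastic line
#' weighted by c + (1-c) A0(Q) plus a single Lorentzian of half-width
#' gamma carrying the remaining (1-c)(1-A0(Q)) weight, all attenuated
#' by a Debye-Waller factor exp(-<u^2> Q^2).
#'
#' @param gamma Lorentzian HWHM (meV), >= 0 (0 = fully elastic limit).
#' @param radius Jump-circle radius r (A), > 0. Default 1.03 A, the
#'   hydrogen distance from the C3 axis of a standard methyl group.
#' @param immobile_fraction Fraction c of hydrogens static on the
#'   instrumental timescale, in [0, 1].
#' @param msd Debye-Waller mean-square displacement <u^2> (A^2), >= 0.
#' @param amplitude Overall intensity scale, > 0.
#' @return An object of class `three_site_model`.
#' @export
three_site_model <- function(gamma, radius = 1.03, immobile_fraction = 0,
                             msd = 0, amplitude = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop_domain("'gamma' must be a single non-negative number (meV)")
  if (!is.numeric(radius) || radius <= 0)
    stop_domain("'radius' must be positive (A)")
  if (!is.numeric(immobile_fraction) || immobile_fraction < 0 || immobile_fraction > 1)
    stop_domain("'immobile_fraction' must lie in [0, 1]")
  if (!is.numeric(msd) || msd < 0)
    stop_domain("'msd' must be non-negative (A^2)")
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop_domain("'amplitude' must be positive")
  structure(
    list(gamma = gamma, radius = radius, immobile_fraction = immobile_fraction,
         msd = msd, amplitude = amplitude),
    class = "three_site_model")
}

#' Rotation-rate distribution scattering model
#'
#' Extension of [three_site_model()] for disordered solids: the single
#' Lorentzian half-width is replaced by a log-normal-weighted mixture
#' of `n_components` Lorentzians spaced uniformly in log(HWHM). The
#' grid spans log(gamma_center) +/- sigma_log * sqrt(2 log(1/cutoff)),
#' i.e. it is truncated where the log-normal density falls to `cutoff`
#' times its maximum.
#'
#' @param gamma_center Geometric center of the HWHM distribution (meV), > 0.
#' @param sigma_log Log-normal standard deviation s (natural-log units), >= 0.
#'   0 collapses the mixture to a single Lorentzian at `gamma_center`.
#' @param n_components Number of mixture components L (odd, >= 3).
#' @param cutoff Relative density cut-off A_min in (0, 1).
#' @param radius,immobile_fraction,msd,amplitude As in [three_site_model()].
#' @return An object of class `rate_distribution_model`.
#' @export
rate_distribution_model <- function(gamma_center, sigma_log,
                                    n_components = 21L, cutoff = 0.1,
                                    radius = 1.03, immobile_fraction = 0,
                                    msd = 0, amplitude = 1) {
  if (!is.numeric(gamma_center) || gamma_center <= 0)
    stop_domain("'gamma_center' must be positive (meV)")
  if (!is.numeric(sigma_log) || sigma_log < 0)
    stop_domain("'sigma_log' must be non-negative")
  n_components <- as.integer(n_components)
  if (n_components < 3L || n_components %% 2L == 0L)
    stop_domain("'n_components' must be odd and >= 3")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop_domain("'cutoff' must lie in (0, 1)")
  base <- three_site_model(gamma = gamma_center, radius = radius,
                           immobile_fraction = immobile_fraction,
                           msd = msd, amplitude = amplitude)
  structure(
    list(gamma_center = gamma_center, sigma_log = sigma_log,
         n_components = n_components, cutoff = cutoff,
         radius = base$radius, immobile_fraction = base$immobile_fraction,
         msd = base$msd, amplitude = base$amplitude),
    class = "rate_distribution_model")
}

#' Instrument resolution function
#'
#' Unit-area line shape on an energy-transfer grid, playing the role of
#' a vanadium elastic-standard measurement. Usually built with
#' [generate_resolution()].
#'
#' @param omega Energy grid (meV), uniform.
#' @param values Non-negative line-shape values integrating to 1.
#' @param fwhm Optional parametric FWHM (meV) recorded for reference.
#' @return An object of class `resolution_function`.
#' @export
resolution_function <- function(omega, values, fwhm = NA_real_) {
  omega <- as.numeric(omega); values <- as.numeric(values)
  if (length(omega) != length(values))
    stop_domain("'omega' and 'values' must have equal length")
  d <- diff(omega)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop_domain("resolution grid must be strictly increasing and uniform")
  if (any(values < 0))
    stop_domain("resolution values must be non-negative")
  area <- sum(values) * d[1L]
  if (abs(area - 1) > 1e-6)
    stop_domain(sprintf("resolution must integrate to 1 (got %.8f)", area))
  structure(list(omega = omega, values = values, fwhm = fwhm),
            class = "resolution_function")
}

#' QENS spectrum at a single momentum transfer
#'
#' @param q Momentum transfer (A^-1), > 0.
#' @param omega Energy-transfer grid (meV), uniform.
#' @param intensity S(Q, omega) values, finite.
#' @param uncertainty Optional 1-sigma uncertainties, > 0 where given.
#' @param resolution Optional attached [resolution_function()].
#' @param metadata Named list of provenance information.
#' @return An object of class `qens_spectrum`.
#' @export
qens_spectrum <- function(q, omega, intensity, uncertainty = NULL,
                          resolution = NULL, metadata = list()) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop_domain("'q' must be a single positive number (A^-1)")
  omega <- as.numeric(omega); intensity <- as.numeric(intensity)
  if (length(omega) != length(intensity))
    stop_domain("'omega' and 'intensity' must have equal length")
  d <- diff(omega)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop_domain("'omega' must be strictly increasing and uniform")
  if (any(!is.finite(intensity)))
    stop_domain("'intensity' must be finite everywhere")
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (length(uncertainty) != length(omega))
      stop_domain("'uncertainty' must match 'omega' in length")
    if (any(!is.finite(uncertainty)) || any(uncertainty <= 0))
      stop_domain("'uncertainty' must be positive where given")
  }
  structure(
    list(q = q, omega = omega, intensity = intensity,
         uncertainty = uncertainty, resolution = resolution,
         metadata = metadata),
    class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf("QENS spectrum: Q = %.2f A^-1, %d omega points in [%.2f, %.2f] meV\n",
              x$q, length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}
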