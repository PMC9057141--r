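#' Elastic incoherent structure factor of three-site circular jumps
#'
#' A0(Q) = (1/3) [1 + 2 j0(Q r sqrt(3))] with j0(x) = sin(x)/x and
#' j0(0) = 1. The sqrt(3) r factor is the inter-site distance of three
#' equidistant sites on a circle of radius r.
#'
#' @param q Momentum transfer (A^-1), >= 0; vectorized.
#' @param radius Jump-circle radius (A), > 0.
#' @return A0 values (dimensionless). A0(0) = 1 for any radius.
#' @export
eisf_three_site <- function(q, radius) {
  if (any(!is.finite(q)) || any(q < 0))
    stop_domain("'q' must be non-negative and finite (A^-1)")
  if (!is.numeric(radius) || radius <= 0)
    stop_domain("'radius' must be positive (A)")
  x <- q * radius * sqrt(3)
  j0 <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
  (1 + 2 * j0) / 3
}

# Unit-area Lorentzian of HWHM gamma (meV) on an energy grid.
lorentzian <- function(omega, gamma) {
  (gamma / pi) / (omega^2 + gamma^2)
}

#' Ideal (resolution-free) three-site jump scattering law
#'
#' Splits S_ideal(Q, omega) into a symbolic elastic weight and a
#' continuous quasielastic part so that the delta function is only ever
#' realized through the resolution function at convolution time:
#'
#' S_ideal = A exp(-<u^2> Q^2) [ (c + (1-c) A0(Q)) delta(omega)
#'           + (1-c)(1 - A0(Q)) L(omega; Gamma) ]
#'
#' Immobile hydrogens (fraction c) contribute only elastically, which
#' preserves the sum rule: the omega-integral equals
#' amplitude * exp(-<u^2> Q^2) for any c and Gamma. A model with
#' gamma = 0 is fully elastic.
#'
#' @param model A [three_site_model()].
#' @param q Momentum transfer (A^-1).
#' @param omega_grid Energy grid (meV).
#' @return List of class `ideal_scattering`: `elastic_weight` (scalar),
#'   `quasielastic` (vector on `omega_grid`), `omega`, `q`.
#' @export
ideal_scattering_three_site <- function(model, q, omega_grid) {
  stopifnot(inherits(model, "three_site_model"))
  a0 <- eisf_three_site(q, model$radius)
  dw <- model$amplitude * exp(-model$msd * q^2)
  c_im <- model$immobile_fraction
  qe_weight <- (1 - c_im) * (1 - a0)
  if (model$gamma == 0) {
    elastic <- dw
    quasi <- numeric(length(omega_grid))
  } else {
    elastic <- dw * (c_im + (1 - c_im) * a0)
    quasi <- dw * qe_weight * lorentzian(omega_grid, model$gamma)
  }
  structure(list(elastic_weight = elastic, quasielastic = quasi,
                 omega = as.numeric(omega_grid), q = q),
            class = "ideal_scattering")
}

#' Log-spaced Lorentzian half-width grid with log-normal weights
#'
#' Builds the HWHM mixture of the rotation-rate distribution model:
#' L points equally spaced in log(Gamma) over
#' log(gamma_center) +/- sigma_log * sqrt(2 log(1/cutoff)) — the span
#' where a log-normal density of standard deviation `sigma_log` stays
#' above `cutoff` times its maximum — weighted by that density and
#' normalized to sum to 1. With sigma_log = 0 the grid degenerates to
#' a single point at `gamma_center` with weight 1.
#'
#' @param gamma_center Geometric center (meV), > 0.
#' @param sigma_log Log-normal standard deviation (natural logs), >= 0.
#' @param n_components Number of grid points L (odd, >= 3).
#' @param cutoff Relative density cut-off in (0, 1).
#' @return List with `gamma` (meV) and `weights` (sum 1).
#' @export
lognormal_gamma_grid <- function(gamma_center, sigma_log,
                                 n_components = 21L, cutoff = 0.1) {
  if (gamma_center <= 0) stop_domain("'gamma_center' must be positive")
  if (sigma_log < 0) stop_domain("'sigma_log' must be non-negative")
  if (cutoff <= 0 || cutoff >= 1) stop_domain("'cutoff' must be in (0, 1)")
  if (sigma_log == 0) {
    return(list(gamma = gamma_center, weights = 1))
  }
  half <- sigma_log * sqrt(2 * log(1 / cutoff))
  lng <- seq(log(gamma_center) - half, log(gamma_center) + half,
             length.out = as.integer(n_components))
  w <- exp(-(lng - log(gamma_center))^2 / (2 * sigma_log^2))
  list(gamma = exp(lng), weights = w / sum(w))
}

#' Ideal scattering law of the rotation-rate distribution model
#'
#' As [ideal_scattering_three_site()] but with the single Lorentzian
#' replaced by the log-normal-weighted mixture from
#' [lognormal_gamma_grid()]. Because the weights sum to 1, the total
#' quasielastic weight is independent of `sigma_log`, and at
#' sigma_log = 0 the output equals the single-Gamma model exactly.
#'
#' @param model A [rate_distribution_model()].
#' @param q Momentum transfer (A^-1).
#' @param omega_grid Energy grid (meV).
#' @return List of class `ideal_scattering` (see
#'   [ideal_scattering_three_site()]).
#' @export
ideal_scattering_distribution <- function(model, q, omega_grid) {
  stopifnot(inherits(model, "rate_distribution_model"))
  a0 <- eisf_three_site(q, model$radius)
  dw <- model$amplitude * exp(-model$msd * q^2)
  c_im <- model$immobile_fraction
  grid <- lognormal_gamma_grid(model$gamma_center, model$sigma_log,
                               model$n_components, model$cutoff)
  quasi <- numeric(length(omega_grid))
  for (j in seq_along(grid$gamma)) {
    quasi <- quasi + grid$weights[j] * lorentzian(omega_grid, grid$gamma[j])
  }
  quasi <- dw * (1 - c_im) * (1 - a0) * quasi
  elastic <- dw * (c_im + (1 - c_im) * a0)
  structure(list(elastic_weight = elastic, quasielastic = quasi,
                 omega = as.numeric(omega_grid), q = q),
            class = "ideal_scattering")
}

#' Convolve an ideal scattering law with the instrument resolution
#'
#' The symbolic elastic line becomes `elastic_weight * R(omega)`; the
#' continuous quasielastic part is convolved with R by discrete
#' convolution on the common grid (midpoint rule, spacing d-omega).
#' Grids must share their spacing and the resolution grid must be
#' centred (contain omega = 0 support within the spectrum support);
#' no resampling is attempted.
#'
#' @param ideal An `ideal_scattering` object, or a list with elements
#'   `elastic_weight` and `quasielastic`.
#' @param resolution A [resolution_function()] on a grid with the same
#'   spacing, with no more points than the spectrum grid.
#' @param omega_grid Energy grid of the spectrum (meV); defaults to
#'   `ideal$omega`.
#' @return Measured intensity vector on `omega_grid`.
#' @export
convolve_resolution <- function(ideal, resolution, omega_grid = NULL) {
  stopifnot(inherits(resolution, "resolution_function"))
  if (is.null(omega_grid)) omega_grid <- ideal$omega
  omega_grid <- as.numeric(omega_grid)
  d_spec <- diff(omega_grid)
  d_res <- diff(resolution$omega)
  if (abs(d_spec[1L] - d_res[1L]) > 1e-9 * d_spec[1L])
    stop_domain("incompatible grids: spectrum and resolution spacings differ; resample upstream, not here")
  if (length(resolution$omega) > length(omega_grid))
    stop_domain("incompatible grids: resolution support exceeds spectrum support")
  quasi <- ideal$quasielastic
  if (length(quasi) != length(omega_grid))
    stop_domain("'quasielastic' must be sampled on 'omega_grid'")
  dw <- d_spec[1L]
  rv <- resolution$values
  # index of omega = 0 in the resolution grid (nearest point)
  i0 <- which.min(abs(resolution$omega))
  if (abs(resolution$omega[i0]) > 1e-9)
    stop_domain("resolution grid must contain omega = 0")
  full <- stats::convolve(quasi, rev(rv), type = "open") * dw
  # full[k] = dw * sum_i quasi[i] rv[k - i + 1]; the output sample for
  # omega_grid[m] sits at k = m + i0 - 1
  measured_q <- full[seq_along(omega_grid) + i0 - 1L]
  # resolution line shape evaluated on the spectrum grid, centred at 0
  res_on_spec <- approx_centered(resolution, omega_grid)
  ideal$elastic_weight * res_on_spec + measured_q
}

# Resolution values looked up on the spectrum grid (same spacing, so a
# pure index shift; outside the resolution support the value is 0).
approx_centered <- function(resolution, omega_grid) {
  out <- numeric(length(omega_grid))
  i0_res <- which.min(abs(resolution$omega))
  i0_spec <- which.min(abs(omega_grid))
  shift <- i0_spec - i0_res
  idx <- seq_along(resolution$values) + shift
  keep <- idx >= 1L & idx <= length(out)
  out[idx[keep]] <- resolution$values[keep]
  out
}

#' Convert a Lorentzian half-width to a correlation time
#'
#' tau_c = hbar / Gamma with hbar = 0.658212 meV ps: a quasielastic
#' HWHM of 0.658212 meV corresponds to 1 ps. The constant is recorded
#' as an attribute so alternative residence-time conventions can be
#' re-derived from the output.
#'
#' @param gamma HWHM (meV), > 0; vectorized.
#' @return Correlation time(s) in ps, with attribute
#'   `convention = "tau = hbar/gamma, hbar = 0.6582119569 meV ps"`.
#' @export
gamma_to_tau <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop_domain("'gamma' must be positive and finite (meV)")
  structure(.HBAR_MEV_PS / gamma,
            convention = "tau = hbar/gamma, hbar = 0.6582119569 meV ps")
}

#' Correlation-time distribution implied by a rate-distribution model
#'
#' Maps the (Gamma_j, g_j) mixture to tau_j = hbar / Gamma_j with
#' unchanged weights and attaches summary statistics: the weighted
#' geometric mean, the mode (tau at the largest weight), and the
#' support span.
#'
#' @param model A [rate_distribution_model()].
#' @return List of class `correlation_time_distribution` with
#'   `tau_values` (ps, in the order of the increasing Gamma grid, hence
#'   strictly decreasing), `weights`, and `summary` (geometric_mean,
#'   mode, span = c(min, max), all in ps).
#' @export
tau_distribution <- function(model) {
  stopifnot(inherits(model, "rate_distribution_model"))
  grid <- lognormal_gamma_grid(model$gamma_center, model$sigma_log,
                               model$n_components, model$cutoff)
  tau <- as.numeric(gamma_to_tau(grid$gamma))
  w <- grid$weights
  structure(
    list(tau_values = tau, weights = w,
         summary = list(
           geometric_mean = exp(sum(w * log(tau))),
           mode = tau[which.max(w)],
           span = range(tau)),
         convention = "tau = hbar/gamma, hbar = 0.6582119569 meV ps"),
    class = "correlation_time_distribution")
}

# ---- global fitting ---------------------------------------------------

.qens_weights <- function(sp) {
  if (!is.null(sp$uncertainty)) 1 / sp$uncertainty else rep(1, length(sp$omega))
}

.qens_fit_setup <- function(spectra, resolution) {
  if (inherits(spectra, "qens_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1L), "qens_spectrum")),
            inherits(resolution, "resolution_function"))
  list(spectra = spectra,
       q = vapply(spectra, function(s) s$q, numeric(1L)),
       weights = lapply(spectra, .qens_weights))
}

#' Global three-site jump fit across momentum transfers
#'
#' Fits a shared Lorentzian half-width Gamma, immobile fraction c and
#' Debye-Waller <u^2> together with one amplitude per spectrum, by
#' weighted Levenberg-Marquardt on all spectra simultaneously. The jump
#' radius is fixed at `config$radius` (default 1.03 A) unless
#' `config$fit_radius` is TRUE. Multi-start over seeded perturbations
#' of the starting point.
#'
#' @param spectra List of [qens_spectrum()] objects (>= 3 Q values
#'   recommended).
#' @param resolution A [resolution_function()].
#' @param config Optional list: `radius`, `fit_radius` (default FALSE),
#'   `start` (named list gamma, c, msd), `n_starts` (default 5).
#' @param seed Integer seed for the multi-start perturbations.
#' @return Object of class `qens_fit` with `model` (three_site_model,
#'   amplitude = 1), `amplitudes` (per Q), `radius`,
#'   `parameter_uncertainties`, `residual_norm`, `converged`,
#'   `warnings`, `per_q_residual`.
#' @export
fit_three_site <- function(spectra, resolution, config = list(), seed = 1L) {
  st <- .qens_fit_setup(spectra, resolution)
  radius <- config$radius %||% 1.03
  fit_radius <- isTRUE(config$fit_radius)
  n_starts <- config$n_starts %||% 5L
  nq <- length(st$spectra)
  amp0 <- vapply(st$spectra, function(s) sum(s$intensity) * diff(s$omega[1:2]),
                 numeric(1L))
  start <- config$start %||% list()
  gamma0 <- start$gamma %||% (resolution$fwhm * 5)
  c0 <- start$c %||% 0.5
  msd0 <- start$msd %||% 0.01
  # parameters: log gamma, logit-ish c (bounded directly), msd, [log r], log amps
  par0 <- c(log(gamma0), c0, msd0, if (fit_radius) log(radius), log(amp0))
  lower <- c(log(1e-5), 0, 0, if (fit_radius) log(0.3), rep(log(1e-8), nq))
  upper <- c(log(50), 1, 2, if (fit_radius) log(3), rep(log(1e8), nq))
  np_shared <- 3L + as.integer(fit_radius)
  build <- function(par, i) {
    r <- if (fit_radius) exp(par[4L]) else radius
    amp <- exp(par[np_shared + i])
    three_site_model(gamma = exp(par[1L]), radius = r,
                     immobile_fraction = min(max(par[2L], 0), 1),
                     msd = max(par[3L], 0), amplitude = amp)
  }
  resid_fn <- function(par) {
    unlist(lapply(seq_len(nq), function(i) {
      sp <- st$spectra[[i]]
      m <- build(par, i)
      ideal <- ideal_scattering_three_site(m, sp$q, sp$omega)
      st$weights[[i]] * (convolve_resolution(ideal, resolution, sp$omega) -
                           sp$intensity)
    }))
  }
  out <- .qens_lm_multistart(resid_fn, par0, lower, upper, seed, n_starts)
  fit <- out$fit; warnings <- character()
  gamma_hat <- exp(fit$par[1L])
  if (is.finite(resolution$fwhm) && gamma_hat < resolution$fwhm / 10)
    warnings <- c(warnings, "unresolved: fitted HWHM below resolution_fwhm/10")
  if (fit$par[2L] >= 1 - 1e-9)
    warnings <- c(warnings, "degenerate: immobile fraction at 1 (elastic-only)")
  per_q <- vapply(seq_len(nq), function(i) {
    sp <- st$spectra[[i]]
    m <- build(fit$par, i)
    ideal <- ideal_scattering_three_site(m, sp$q, sp$omega)
    sum((st$weights[[i]] * (convolve_resolution(ideal, resolution, sp$omega) -
                              sp$intensity))^2)
  }, numeric(1L))
  structure(
    list(model = three_site_model(gamma = gamma_hat,
                                  radius = if (fit_radius) exp(fit$par[4L]) else radius,
                                  immobile_fraction = min(max(fit$par[2L], 0), 1),
                                  msd = max(fit$par[3L], 0), amplitude = 1),
         amplitudes = stats::setNames(exp(fit$par[np_shared + seq_len(nq)]),
                                      sprintf("q=%.2f", st$q)),
         radius = if (fit_radius) exp(fit$par[4L]) else radius,
         parameter_uncertainties = out$se,
         residual_norm = out$rss, converged = out$converged,
         warnings = warnings, per_q_residual = per_q, seed = seed),
    class = "qens_fit")
}

#' Global rotation-rate distribution fit across momentum transfers
#'
#' Fits gamma_center, sigma_log, immobile fraction and Debye-Waller
#' <u^2> (shared) plus per-Q amplitudes of the log-normal Lorentzian
#' mixture model, with L and the cut-off fixed from `config` (defaults
#' 21 and 0.1). The nested single-Gamma fit ([fit_three_site()]) is run
#' as well and its residual attached for model comparison.
#'
#' @param spectra List of [qens_spectrum()] objects.
#' @param resolution A [resolution_function()].
#' @param config Optional list: `n_components` (21), `cutoff` (0.1),
#'   `radius` (1.03), `fit_radius` (FALSE), `start`, `n_starts` (5).
#' @param seed Integer seed.
#' @return Object of class `qens_distribution_fit` with `model`
#'   (rate_distribution_model, amplitude = 1), `amplitudes`,
#'   `parameter_uncertainties`, `residual_norm`, `converged`,
#'   `warnings`, `single_gamma_fit` (the nested [fit_three_site()]
#'   result), `residual_ratio`.
#' @export
fit_distribution <- function(spectra, resolution, config = list(), seed = 1L) {
  st <- .qens_fit_setup(spectra, resolution)
  radius <- config$radius %||% 1.03
  fit_radius <- isTRUE(config$fit_radius)
  L <- as.integer(config$n_components %||% 21L)
  cutoff <- config$cutoff %||% 0.1
  n_starts <- config$n_starts %||% 5L
  nq <- length(st$spectra)
  amp0 <- vapply(st$spectra, function(s) sum(s$intensity) * diff(s$omega[1:2]),
                 numeric(1L))
  start <- config$start %||% list()
  gamma0 <- start$gamma_center %||% (resolution$fwhm * 5)
  s0 <- start$sigma_log %||% 0.7
  c0 <- start$c %||% 0.5
  msd0 <- start$msd %||% 0.01
  par0 <- c(log(gamma0), s0, c0, msd0, if (fit_radius) log(radius), log(amp0))
  lower <- c(log(1e-5), 0, 0, 0, if (fit_radius) log(0.3), rep(log(1e-8), nq))
  upper <- c(log(50), 4, 1, 2, if (fit_radius) log(3), rep(log(1e8), nq))
  np_shared <- 4L + as.integer(fit_radius)
  build <- function(par, i) {
    r <- if (fit_radius) exp(par[5L]) else radius
    rate_distribution_model(
      gamma_center = exp(par[1L]), sigma_log = max(par[2L], 0),
      n_components = L, cutoff = cutoff, radius = r,
      immobile_fraction = min(max(par[3L], 0), 1), msd = max(par[4L], 0),
      amplitude = exp(par[np_shared + i]))
  }
  resid_fn <- function(par) {
    unlist(lapply(seq_len(nq), function(i) {
      sp <- st$spectra[[i]]
      m <- build(par, i)
      ideal <- ideal_scattering_distribution(m, sp$q, sp$omega)
      st$weights[[i]] * (convolve_resolution(ideal, resolution, sp$omega) -
                           sp$intensity)
    }))
  }
  out <- .qens_lm_multistart(resid_fn, par0, lower, upper, seed, n_starts)
  fit <- out$fit; warnings <- character()
  gamma_hat <- exp(fit$par[1L])
  if (is.finite(resolution$fwhm) && gamma_hat < resolution$fwhm / 10)
    warnings <- c(warnings, "unresolved: fitted center HWHM below resolution_fwhm/10")
  single <- fit_three_site(st$spectra, resolution,
                           config = c(config[intersect(names(config),
                                                       c("radius", "fit_radius",
                                                         "n_starts"))],
                                      list(start = list(gamma = gamma_hat,
                                                        c = fit$par[3L],
                                                        msd = fit$par[4L]))),
                           seed = seed)
  structure(
    list(model = rate_distribution_model(
           gamma_center = gamma_hat, sigma_log = max(fit$par[2L], 0),
           n_components = L, cutoff = cutoff,
           radius = if (fit_radius) exp(fit$par[5L]) else radius,
           immobile_fraction = min(max(fit$par[3L], 0), 1),
           msd = max(fit$par[4L], 0), amplitude = 1),
         amplitudes = stats::setNames(exp(fit$par[np_shared + seq_len(nq)]),
                                      sprintf("q=%.2f", st$q)),
         parameter_uncertainties = out$se,
         residual_norm = out$rss, converged = out$converged,
         warnings = warnings, single_gamma_fit = single,
         residual_ratio = out$rss / single$residual_norm, seed = seed),
    class = "qens_distribution_fit")
}

.qens_lm_multistart <- function(resid_fn, par0, lower, upper, seed, n_starts) {
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1L) return(par0)
      p <- par0 + stats::rnorm(length(par0), 0, 0.25 * pmax(abs(par0), 0.5))
      pmin(pmax(p, lower), upper)
    })
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("QENS fit failed from every start", call. = FALSE)
  fit <- best$fit
  se <- tryCatch({
    np <- length(fit$par)
    cov <- solve(fit$hessian) * best$rss /
      max(length(fit$fvec) - np, 1L)
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) NULL)
  list(fit = fit, rss = best$rss, converged = fit$info %in% 1:4, se = se)
}

#' @export
print.qens_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("Three-site jump fit: Gamma = %.4g meV (tau = %.3g ps), c = %.3f, <u^2> = %.3g A^2, RSS = %.4g%s\n",
              m$gamma, as.numeric(gamma_to_tau(max(m$gamma, 1e-12))),
              m$immobile_fraction, m$msd, x$residual_norm,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
print.qens_distribution_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("Rate-distribution fit: Gamma_center = %.4g meV, s = %.3f, c = %.3f, <u^2> = %.3g A^2, RSS = %.4g (single-Gamma RSS %.4g)\n",
              m$gamma_center, m$sigma_log, m$immobile_fraction, m$msd,
              x$residual_norm, x$single_gamma_fit$residual_norm))
  invisible(x)
}
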