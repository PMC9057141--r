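#' Arrhenius correlation time
#'
#' tau_c(T) = tau0 * exp(EA / (R T)), with EA in kJ/mol converted to
#' J/mol internally. Monotonically decreasing in temperature.
#'
#' @param process An [arrhenius_process()].
#' @param temperature Temperature (K), > 0; vectorized.
#' @return Correlation time(s) in seconds.
#' @examples
#' p <- arrhenius_process(1e-13, 13.76, 1e9)
#' arrhenius_tau(p, 300)  # about 2.49e-11 s
#' @export
arrhenius_tau <- function(process, temperature) {
  stopifnot(inherits(process, "arrhenius_process"))
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_domain("temperature must be positive and finite (K)")
  process$tau0 * exp(process$activation_energy * 1000 / (.R_GAS * temperature))
}

#' BPP spin-lattice relaxation rate for one process
#'
#' 1/T1 = C * ( tau / (1 + omega0^2 tau^2) + 4 tau / (1 + 4 omega0^2 tau^2) ),
#' the classical two-spectral-density form evaluated at the Larmor
#' frequency and its double.
#'
#' @param strength Relaxation constant C (s^-2), > 0.
#' @param tau Correlation time (s), > 0; vectorized.
#' @param omega0 Larmor angular frequency (rad/s), > 0.
#' @return Relaxation rate(s) 1/T1 in s^-1.
#' @export
bpp_rate <- function(strength, tau, omega0) {
  if (!is.numeric(strength) || strength <= 0)
    stop_domain("'strength' must be positive (s^-2)")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop_domain("'tau' must be positive and finite (s)")
  if (!is.numeric(omega0) || omega0 <= 0)
    stop_domain("'omega0' must be positive (rad/s)")
  strength * (tau / (1 + omega0^2 * tau^2) + 4 * tau / (1 + 4 * omega0^2 * tau^2))
}

#' Total relaxation rate of a multi-process model
#'
#' Rates are additive: the total 1/T1 at a temperature is the sum of
#' the BPP rates of all processes, each with its own Arrhenius
#' correlation time.
#'
#' @param model A [relaxation_model()].
#' @param temperature Temperature(s) in K; vectorized.
#' @return Total relaxation rate(s) 1/T1 in s^-1.
#' @export
model_rate <- function(model, temperature) {
  stopifnot(inherits(model, "relaxation_model"))
  omega0 <- 2 * pi * model$larmor_frequency * 1e6
  rate <- numeric(length(temperature))
  for (p in model$processes) {
    rate <- rate + bpp_rate(p$strength, arrhenius_tau(p, temperature), omega0)
  }
  rate
}

# Reduced BPP rate f(x) = x/(1+x^2) + 4x/(1+4x^2), x = omega0 * tau.
bpp_reduced_rate <- function(x) x / (1 + x^2) + 4 * x / (1 + 4 * x^2)

#' T1-minimum condition of the BPP model
#'
#' The spin-lattice relaxation rate of a single BPP process, viewed as
#' a function of x = omega0 * tau_c, is maximal (T1 minimal) at the
#' maximizer of f(x) = x/(1+x^2) + 4x/(1+4x^2). This function locates
#' that maximizer numerically to at least 6 significant digits; it
#' rounds to 0.616.
#'
#' @return List with `x_star` (the dimensionless maximizer) and
#'   `f_star` (the reduced rate at the maximizer, about 1.4252).
#' @examples
#' round(t1_minimum_condition()$x_star, 3)  # 0.616
#' @export
t1_minimum_condition <- function() {
  opt <- stats::optimize(bpp_reduced_rate, interval = c(1e-3, 10),
                         maximum = TRUE, tol = 1e-12)
  list(x_star = opt$maximum, f_star = opt$objective)
}

#' Temperature of a process's T1 minimum
#'
#' Solves omega0 * tau_c(T) = x_star for T by bracketed root finding on
#' [1, 2000] K. Because tau_c is strictly monotone in T the root is
#' unique when it exists; a process with EA = 0 (constant tau) has no
#' minimum and raises an error.
#'
#' @param process An [arrhenius_process()].
#' @param larmor_frequency Proton resonance frequency (MHz).
#' @return Temperature of the T1 minimum (K).
#' @export
predict_minimum_temperature <- function(process, larmor_frequency) {
  stopifnot(inherits(process, "arrhenius_process"))
  omega0 <- 2 * pi * larmor_frequency * 1e6
  x_star <- t1_minimum_condition()$x_star
  # log(omega0 * tau(T) / x_star) computed without evaluating exp(EA/RT)
  g <- function(T) {
    log(omega0 * process$tau0 / x_star) +
      process$activation_energy * 1000 / (.R_GAS * T)
  }
  lo <- g(1); hi <- g(2000)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop_domain("no T1 minimum in [1, 2000] K for this process (omega0*tau does not cross the minimum condition)")
  stats::uniroot(g, c(1, 2000), tol = 1e-10)$root
}

#' Heuristic starting values for a multi-process relaxation fit
#'
#' Locates local minima of log T1 versus temperature, assigns one
#' process to the highest-temperature minimum and spreads the
#' remaining processes over the lowest-temperature minimum with a
#' geometric ladder of activation energies, mirroring how practitioners
#' decompose a two-minimum curve into one high-T plus several low-T
#' processes. tau0 is initialized at `tau0_guess` and C from the depth
#' of the assigned minimum.
#'
#' @param curve A [relaxation_curve()].
#' @param n_processes Number of processes to initialize.
#' @param larmor_frequency MHz.
#' @param tau0_guess Initial pre-exponential time (s).
#' @param spread Fractional half-range of the low-T EA ladder.
#' @return List of `arrhenius_process` objects of length `n_processes`.
#' @export
initial_guess_relaxation <- function(curve, n_processes, larmor_frequency,
                                     tau0_guess = 1e-12, spread = 0.45) {
  stopifnot(inherits(curve, "relaxation_curve"))
  omega0 <- 2 * pi * larmor_frequency * 1e6
  x_star <- t1_minimum_condition()$x_star
  f_star <- bpp_reduced_rate(x_star)
  Tv <- curve$temperatures; lt1 <- log(curve$t1_values)
  n <- length(Tv)
  # local minima of log T1 on the sampled grid (interior points)
  is_min <- c(FALSE, diff(sign(diff(lt1))) > 0, FALSE)
  idx <- which(is_min)
  if (length(idx) == 0L) idx <- which.min(lt1)
  # EA consistent with a minimum at T_min for the guessed tau0
  ea_at <- function(Tmin) {
    ea <- .R_GAS * Tmin * log(x_star / (omega0 * tau0_guess)) / 1000
    max(ea, 0.5)
  }
  c_at <- function(i) omega0 / (curve$t1_values[i] * f_star)
  idx <- idx[order(Tv[idx], decreasing = TRUE)]
  hi <- idx[1L]; lo <- idx[length(idx)]
  out <- vector("list", n_processes)
  out[[1L]] <- arrhenius_process(tau0_guess, ea_at(Tv[hi]), c_at(hi),
                                 label = "high-T")
  if (n_processes > 1L) {
    ea_lo <- ea_at(Tv[lo])
    k <- n_processes - 1L
    fac <- if (k == 1L) 1 else exp(seq(log(1 - spread), log(1 + spread),
                                       length.out = k))
    for (j in seq_len(k)) {
      out[[j + 1L]] <- arrhenius_process(tau0_guess, ea_lo * fac[j],
                                         c_at(lo) / k,
                                         label = sprintf("low-T %d", j))
    }
  }
  out
}

# Parameter mapping between a process list and the optimizer vector.
# EAs are always per process; log10 tau0 and log10 C can be tied within
# share groups (one value per group instead of per process). The vector
# layout is [EA_1..EA_n, log10tau0 per tau0-unit, log10C per C-unit].
.relax_map <- function(n_processes, share = NULL) {
  groups <- share$groups %||% seq_len(n_processes)
  stopifnot(length(groups) == n_processes)
  tau0_units <- if (isTRUE(share$tau0)) match(groups, unique(groups))
                else seq_len(n_processes)
  c_units <- if (isTRUE(share$strength)) match(groups, unique(groups))
             else seq_len(n_processes)
  n_tau0 <- max(tau0_units); n_c <- max(c_units)
  list(n = n_processes, tau0_units = tau0_units, c_units = c_units,
       idx_ea = seq_len(n_processes),
       idx_tau0 = n_processes + seq_len(n_tau0),
       idx_c = n_processes + n_tau0 + seq_len(n_c),
       n_par = n_processes + n_tau0 + n_c)
}

.pack_relax <- function(processes, map) {
  ea <- vapply(processes, function(p) p$activation_energy, numeric(1L))
  lt <- vapply(processes, function(p) log10(p$tau0), numeric(1L))
  lc <- vapply(processes, function(p) log10(p$strength), numeric(1L))
  par <- numeric(map$n_par)
  par[map$idx_ea] <- ea
  for (u in seq_along(map$idx_tau0))
    par[map$idx_tau0[u]] <- mean(lt[map$tau0_units == u])
  for (u in seq_along(map$idx_c))
    par[map$idx_c[u]] <- mean(lc[map$c_units == u])
  par
}

.unpack_relax <- function(par, map, labels = NULL) {
  lapply(seq_len(map$n), function(i) {
    arrhenius_process(10^par[map$idx_tau0[map$tau0_units[i]]],
                      max(par[map$idx_ea[i]], 0),
                      10^par[map$idx_c[map$c_units[i]]],
                      label = if (is.null(labels)) "" else labels[i])
  })
}

#' Fit a multi-process BPP model to a T1 curve
#'
#' Weighted least squares on log T1 versus temperature (the space in
#' which such curves are conventionally plotted and judged), using
#' Levenberg-Marquardt with box bounds. Each process contributes three
#' parameters (log10 tau0, EA, log10 C). Multi-start: the supplied (or
#' heuristic) initial guesses are used as the first start and
#' `n_starts - 1` seeded log-space perturbations follow; the best
#' residual wins, ties broken by the lowest total activation energy.
#'
#' @param curve A [relaxation_curve()].
#' @param n_processes Number of BPP processes to fit (>= 1).
#' @param larmor_frequency MHz; defaults to `curve$metadata$larmor_frequency`
#'   or 25 MHz.
#' @param initial_guesses Optional list of `arrhenius_process` starting
#'   values (length `n_processes`); defaults to
#'   [initial_guess_relaxation()].
#' @param bounds Optional list with elements `lower`, `upper`: named
#'   numeric vectors with entries `log10_tau0`, `ea`, `log10_c` applied
#'   to every process.
#' @param seed Integer seed for the multi-start perturbations.
#' @param n_starts Number of starts (>= 1).
#' @param exclude_below Optional temperature (K); points below it are
#'   omitted from the fit. This is the conventional way to keep
#'   low-temperature relaxation channels of different physical origin
#'   (e.g. hydrogen-bridge proton dynamics) out of a methyl-group fit.
#' @param share Optional list tying parameters across processes:
#'   `groups` (integer vector of length `n_processes` assigning each
#'   process to a group), and flags `tau0` and `strength`; a TRUE flag
#'   makes that parameter common within each group. Activation
#'   energies are always free. Typical use: one high-T process plus a
#'   low-T group representing a barrier distribution of a single
#'   methyl species, `share = list(groups = c(1, rep(2, 5)),
#'   tau0 = TRUE, strength = TRUE)`.
#' @param perturb_sd Standard deviations of the multi-start
#'   perturbations on (EA, log10 tau0, log10 C).
#' @return An object of class `relaxation_fit` with elements `model`,
#'   `parameter_uncertainties`, `residual_norm` (weighted RSS),
#'   `converged`, `n_points`, `warnings`, `weighting`, `seed`.
#' @export
fit_relaxation <- function(curve, n_processes, larmor_frequency = NULL,
                           initial_guesses = NULL, bounds = NULL,
                           seed = 1L, n_starts = 8L, exclude_below = NULL,
                           share = NULL, perturb_sd = c(0.3, 0.25, 0.25)) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (n_processes < 1L) stop_domain("'n_processes' must be >= 1")
  if (is.null(larmor_frequency))
    larmor_frequency <- curve$metadata$larmor_frequency %||% 25.0
  keep <- rep(TRUE, length(curve$temperatures))
  if (!is.null(exclude_below)) keep <- curve$temperatures >= exclude_below
  Tv <- curve$temperatures[keep]
  lt1_obs <- log(curve$t1_values[keep])
  w <- if (!is.null(curve$t1_uncertainties)) {
    rel <- curve$t1_uncertainties[keep] / curve$t1_values[keep]
    1 / pmax(rel, 1e-6)
  } else rep(1, length(Tv))
  warnings <- character()
  map <- .relax_map(n_processes, share)
  n_par <- map$n_par
  if (length(Tv) / n_par < 3)
    warnings <- c(warnings, sprintf(
      "identifiability: %d points for %d parameters (ratio %.1f < 3)",
      length(Tv), n_par, length(Tv) / n_par))
  if (is.null(initial_guesses)) {
    initial_guesses <- initial_guess_relaxation(curve, n_processes,
                                                larmor_frequency)
  }
  if (length(initial_guesses) != n_processes)
    stop_domain("'initial_guesses' must have length 'n_processes'")
  labels <- vapply(initial_guesses, function(p) p$label, character(1L))
  par0 <- .pack_relax(initial_guesses, map)
  lower1 <- c(log10_tau0 = -16, ea = 0, log10_c = 4)
  upper1 <- c(log10_tau0 = -8, ea = 60, log10_c = 13)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower1[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper1[names(bounds$upper)] <- bounds$upper
  }
  lower <- numeric(n_par); upper <- numeric(n_par)
  lower[map$idx_ea] <- lower1[["ea"]]; upper[map$idx_ea] <- upper1[["ea"]]
  lower[map$idx_tau0] <- lower1[["log10_tau0"]]
  upper[map$idx_tau0] <- upper1[["log10_tau0"]]
  lower[map$idx_c] <- lower1[["log10_c"]]; upper[map$idx_c] <- upper1[["log10_c"]]
  sd_vec <- numeric(n_par)
  sd_vec[map$idx_ea] <- perturb_sd[1L]
  sd_vec[map$idx_tau0] <- perturb_sd[2L]
  sd_vec[map$idx_c] <- perturb_sd[3L]
  resid_fn <- function(par) {
    model <- relaxation_model(.unpack_relax(par, map), larmor_frequency)
    w * (log(1 / model_rate(model, Tv)) - lt1_obs)
  }
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1L) return(par0)
      p <- par0 + stats::rnorm(n_par, 0, sd_vec)
      pmin(pmax(p, lower), upper)
    })
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    tot_ea <- sum(vapply(.unpack_relax(fit$par, map), function(p)
      p$activation_energy, numeric(1L)))
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && tot_ea < best$tot_ea)) {
      best <- list(fit = fit, rss = rss, tot_ea = tot_ea)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(model = relaxation_model(initial_guesses, larmor_frequency),
           parameter_uncertainties = NULL, residual_norm = Inf,
           converged = FALSE, n_points = length(Tv), warnings =
             c(warnings, "no start converged"),
           weighting = "relative, on log T1", seed = seed),
      class = "relaxation_fit"))
  }
  fit <- best$fit
  converged <- fit$info %in% 1:4
  procs <- .unpack_relax(fit$par, map, labels)
  # order processes by decreasing activation energy for stable reporting
  ord <- order(vapply(procs, function(p) p$activation_energy, numeric(1L)),
               decreasing = TRUE)
  procs <- procs[ord]
  unc <- NULL
  if (converged) {
    cov <- tryCatch(solve(fit$hessian) * best$rss /
                      max(length(Tv) - n_par, 1L),
                    error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(pmax(diag(cov), 0))
      unc <- cbind(ea = se[map$idx_ea],
                   log10_tau0 = se[map$idx_tau0][map$tau0_units],
                   log10_c = se[map$idx_c][map$c_units])
      unc <- unc[ord, , drop = FALSE]
    }
  }
  structure(
    list(model = relaxation_model(procs, larmor_frequency),
         parameter_uncertainties = unc, residual_norm = best$rss,
         converged = converged, n_points = length(Tv),
         warnings = warnings, weighting = "relative, on log T1",
         seed = seed),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("BPP relaxation fit: %d process(es), weighted RSS = %.4g, %s\n",
              length(x$model$processes), x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  for (p in x$model$processes) print(p)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
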