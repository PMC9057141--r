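# Tabular files: '#'-prefixed metadata lines ("# key: value"), then a
# header row, tab-separated numeric columns. Units live in the column
# names and are validated at read time.

.write_meta <- function(con, meta) {
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v))
      writeLines(sprintf("# %s: %.17g", k, v), con)
    else if (is.character(v) && length(v) == 1L)
      writeLines(sprintf("# %s: %s", k, v), con)
  }
}

.read_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3L]))
      out[[trimws(m[2L])]] <- if (is.na(val)) m[3L] else val
    }
  }
  out
}

.read_table_checked <- function(path, expected_header) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 2L)
    stop_domain(sprintf("%s: no data rows found", path))
  header <- strsplit(trimws(lines[body_idx[1L]]), "\t")[[1L]]
  if (!all(expected_header %in% header))
    stop_domain(sprintf(
      "%s: missing units header; expected columns %s, found %s",
      path, paste(expected_header, collapse = ", "),
      paste(header, collapse = ", ")))
  rows <- body_idx[-1L]
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(header))
  for (i in seq_along(rows)) {
    cells <- strsplit(trimws(lines[rows[i]]), "\t")[[1L]]
    if (length(cells) != length(header))
      stop_domain(sprintf("%s: line %d has %d cells, expected %d",
                          path, rows[i], length(cells), length(header)))
    v <- suppressWarnings(as.numeric(cells))
    if (any(is.na(v) & cells != "NA"))
      stop_domain(sprintf("%s: malformed numeric cell at line %d", path, rows[i]))
    vals[i, ] <- v
  }
  colnames(vals) <- header
  list(values = vals, metadata = .read_meta(lines))
}

#' Write / read a T1 relaxation curve
#'
#' Tab-separated with columns `temperature_K`, `t1_s` and optionally
#' `t1_sd_s`, preceded by '#'-prefixed metadata (Larmor frequency,
#' provenance). Reading a file in descending temperature order
#' succeeds with a warning; the curve is stored sorted.
#'
#' @param curve A [relaxation_curve()].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve`
#'   returns a [relaxation_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(con, c(list(type = "relaxation_curve"),
                     curve$metadata[vapply(curve$metadata, function(v)
                       is.character(v) || (is.numeric(v) && length(v) == 1L),
                       logical(1L))]))
  has_sd <- !is.null(curve$t1_uncertainties)
  writeLines(paste(c("temperature_K", "t1_s", if (has_sd) "t1_sd_s"),
                   collapse = "\t"), con)
  for (i in seq_along(curve$temperatures)) {
    writeLines(paste(
      c(sprintf("%.17g", curve$temperatures[i]),
        sprintf("%.17g", curve$t1_values[i]),
        if (has_sd) sprintf("%.17g", curve$t1_uncertainties[i])),
      collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  tab <- .read_table_checked(path, c("temperature_K", "t1_s"))
  v <- tab$values
  if (is.unsorted(v[, "temperature_K"]))
    warning("temperatures were not ascending; curve sorted on read",
            call. = FALSE)
  relaxation_curve(
    v[, "temperature_K"], v[, "t1_s"],
    t1_uncertainties = if ("t1_sd_s" %in% colnames(v)) v[, "t1_sd_s"] else NULL,
    metadata = tab$metadata)
}

#' Write / read a saturation-recovery trace
#'
#' Columns `delay_s`, `mz` and optionally `mz_sd`; the timestamp (days
#' since amorphization) is carried in the metadata header.
#'
#' @param trace A [recovery_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace`
#'   returns a [recovery_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recovery_trace"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- list(type = "recovery_trace")
  if (is.finite(trace$timestamp)) meta$timestamp_days <- trace$timestamp
  .write_meta(con, meta)
  has_sd <- !is.null(trace$uncertainties)
  writeLines(paste(c("delay_s", "mz", if (has_sd) "mz_sd"), collapse = "\t"),
             con)
  for (i in seq_along(trace$delays)) {
    writeLines(paste(
      c(sprintf("%.17g", trace$delays[i]), sprintf("%.17g", trace$magnetization[i]),
        if (has_sd) sprintf("%.17g", trace$uncertainties[i])),
      collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- .read_table_checked(path, c("delay_s", "mz"))
  v <- tab$values
  recovery_trace(
    v[, "delay_s"], v[, "mz"],
    uncertainties = if ("mz_sd" %in% colnames(v)) v[, "mz_sd"] else NULL,
    timestamp = tab$metadata$timestamp_days %||% NA_real_,
    metadata = tab$metadata)
}

#' Write / read QENS spectra
#'
#' One file per momentum transfer (`q_<value>.dat` under `dir`) with
#' columns `omega_meV`, `intensity` and optionally `intensity_sd`;
#' the Q value and resolution FWHM travel in the metadata header.
#' `write_resolution`/`read_resolution` handle the resolution line
#' shape the same way.
#'
#' @param spectra List of [qens_spectrum()] objects.
#' @param dir Directory (created if needed).
#' @return `write_spectra` returns the file paths invisibly;
#'   `read_spectra` returns a list of [qens_spectrum()] objects sorted
#'   by Q.
#' @export
write_spectra <- function(spectra, dir) {
  if (inherits(spectra, "qens_spectrum")) spectra <- list(spectra)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(spectra, function(sp) {
    path <- file.path(dir, sprintf("q_%.3f.dat", sp$q))
    con <- file(path, "w"); on.exit(close(con))
    meta <- list(type = "qens_spectrum", q_A_inv = sp$q)
    if (!is.null(sp$resolution) && is.finite(sp$resolution$fwhm))
      meta$resolution_fwhm_meV <- sp$resolution$fwhm
    .write_meta(con, meta)
    has_sd <- !is.null(sp$uncertainty)
    writeLines(paste(c("omega_meV", "intensity", if (has_sd) "intensity_sd"),
                     collapse = "\t"), con)
    for (i in seq_along(sp$omega)) {
      writeLines(paste(
        c(sprintf("%.17g", sp$omega[i]), sprintf("%.17g", sp$intensity[i]),
          if (has_sd) sprintf("%.17g", sp$uncertainty[i])),
        collapse = "\t"), con)
    }
    path
  }, character(1L))
  invisible(paths)
}

#' @rdname write_spectra
#' @param resolution A [resolution_function()] to attach to every
#'   spectrum read (optional).
#' @export
read_spectra <- function(dir, resolution = NULL) {
  files <- sort(list.files(dir, pattern = "^q_.*\\.dat$", full.names = TRUE))
  if (length(files) == 0L)
    stop_domain(sprintf("no spectrum files (q_*.dat) found in %s", dir))
  sps <- lapply(files, function(path) {
    tab <- .read_table_checked(path, c("omega_meV", "intensity"))
    v <- tab$values
    q <- tab$metadata$q_A_inv
    if (is.null(q)) stop_domain(sprintf("%s: missing 'q_A_inv' metadata", path))
    qens_spectrum(
      q, v[, "omega_meV"], v[, "intensity"],
      uncertainty = if ("intensity_sd" %in% colnames(v)) v[, "intensity_sd"] else NULL,
      resolution = resolution, metadata = tab$metadata)
  })
  sps[order(vapply(sps, function(s) s$q, numeric(1L)))]
}

#' @rdname write_spectra
#' @export
write_resolution <- function(resolution, path) {
  stopifnot(inherits(resolution, "resolution_function"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- list(type = "resolution_function")
  if (is.finite(resolution$fwhm)) meta$fwhm_meV <- resolution$fwhm
  .write_meta(con, meta)
  writeLines("omega_meV\tvalue", con)
  for (i in seq_along(resolution$omega)) {
    writeLines(sprintf("%.17g\t%.17g", resolution$omega[i],
                       resolution$values[i]), con)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_resolution <- function(path) {
  tab <- .read_table_checked(path, c("omega_meV", "value"))
  v <- tab$values
  resolution_function(v[, "omega_meV"], v[, "value"],
                      fwhm = tab$metadata$fwhm_meV %||% NA_real_)
}

# ---- pipeline ---------------------------------------------------------

.known_config_keys <- c("seed", "out_dir", "stages", "t1", "recovery",
                        "kinetics", "qens")

#' Run a simulate-and-fit pipeline from a single configuration
#'
#' Executes the requested stages in order and returns a run report.
#' Supported stages:
#' \describe{
#'   \item{`simulate_t1` / `fit_t1`}{Generate the six-process amorphous
#'     T1 scenario curve (or read `config$t1$curve_file`) and refit it.}
#'   \item{`simulate_kinetics` / `kinetics`}{Generate a logistic
#'     recrystallization series and recover the fraction-time curve and
#'     completion time.}
#'   \item{`simulate_qens` / `fit_qens`}{Generate rate-distribution
#'     spectra and refit them (`config$qens$model` chooses
#'     `"three_site"` or `"distribution"`).}
#' }
#' Unknown top-level config keys are rejected. All randomness descends
#' from `config$seed`; rerunning with the same config reproduces the
#' numeric tables byte for byte. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config Named list (or path to a YAML file) with `seed`,
#'   optional `out_dir`, `stages` (character vector), and per-stage
#'   sub-lists `t1`, `kinetics`, `qens`.
#' @return Object of class `run_report`: resolved `config`, `seed`,
#'   per-stage `results`, `versions`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop_domain(sprintf("unknown config keys: %s",
                        paste(unknown, collapse = ", ")))
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate_t1", "fit_t1")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  results <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  state <- new.env(parent = emptyenv())
  for (stage in stages) {
    results[[stage]] <- switch(
      stage,
      simulate_t1 = run_stage(stage, function() {
        cfg <- config$t1 %||% list()
        model <- amorphous_t1_scenario(cfg$larmor_frequency %||% 25.0)
        temps <- seq(cfg$t_min %||% 20, cfg$t_max %||% 300,
                     length.out = cfg$n_temperatures %||% 60L)
        curve <- generate_t1_curve(model$processes, model$larmor_frequency,
                                   temps,
                                   noise_spec(cfg$relative_sd %||% 0.02, seed))
        state$curve <- curve
        if (!is.null(out_dir)) write_curve(curve, file.path(out_dir, "t1_curve.tsv"))
        list(n_points = length(curve$temperatures),
             n_processes = length(model$processes))
      }),
      fit_t1 = run_stage(stage, function() {
        cfg <- config$t1 %||% list()
        curve <- if (!is.null(cfg$curve_file)) read_curve(cfg$curve_file)
                 else state$curve
        if (is.null(curve))
          stop("no T1 curve available: run simulate_t1 first or set t1$curve_file")
        fit <- fit_relaxation(curve, cfg$n_processes %||% 6L, seed = seed,
                              exclude_below = cfg$exclude_below)
        ea <- vapply(fit$model$processes, function(p) p$activation_energy,
                     numeric(1L))
        list(activation_energies_kj_mol = ea,
             residual_norm = fit$residual_norm, converged = fit$converged)
      }),
      simulate_kinetics = run_stage(stage, function() {
        cfg <- config$kinetics %||% list()
        times <- seq(cfg$t_start %||% 7, cfg$t_end %||% 126,
                     by = cfg$dt %||% 7)
        traj <- logistic_trajectory(times)
        state$traces <- generate_recrystallization_series(
          traj, t1_amorphous = cfg$t1_amorphous %||% 0.2,
          t1_crystalline = cfg$t1_crystalline %||% 2.0,
          noise = noise_spec(cfg$relative_sd %||% 0.01, seed))
        list(n_traces = length(state$traces))
      }),
      kinetics = run_stage(stage, function() {
        cfg <- config$kinetics %||% list()
        if (is.null(state$traces))
          stop("no traces available: run simulate_kinetics first")
        kin <- build_kinetics(state$traces, config = c(cfg, list(seed = seed)))
        if (!is.null(out_dir)) {
          utils::write.table(kin$points,
                             file.path(out_dir, "kinetics.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
        list(completion_time_days = kin$completion_time,
             completion_reached = kin$completion_reached,
             n_points = nrow(kin$points))
      }),
      simulate_qens = run_stage(stage, function() {
        cfg <- config$qens %||% list()
        instrument <- instrument_config()
        model <- rate_distribution_model(
          gamma_center = cfg$gamma_center %||% 0.16,
          sigma_log = cfg$sigma_log %||% 1.0,
          immobile_fraction = cfg$immobile_fraction %||% (12 / 18),
          msd = cfg$msd %||% 0.05)
        state$spectra <- generate_qens_spectrum(
          model, instrument, noise_spec(cfg$relative_sd %||% 0.02, seed))
        state$resolution <- generate_resolution(instrument)
        if (!is.null(out_dir))
          write_spectra(state$spectra, file.path(out_dir, "qens"))
        list(n_spectra = length(state$spectra))
      }),
      fit_qens = run_stage(stage, function() {
        cfg <- config$qens %||% list()
        if (is.null(state$spectra))
          stop("no spectra available: run simulate_qens first")
        kind <- cfg$model %||% "distribution"
        if (kind == "three_site") {
          fit <- fit_three_site(state$spectra, state$resolution, seed = seed)
          list(gamma_meV = fit$model$gamma,
               tau_ps = as.numeric(gamma_to_tau(fit$model$gamma)),
               immobile_fraction = fit$model$immobile_fraction,
               residual_norm = fit$residual_norm, converged = fit$converged)
        } else {
          fit <- fit_distribution(state$spectra, state$resolution, seed = seed)
          td <- tau_distribution(fit$model)
          list(gamma_center_meV = fit$model$gamma_center,
               sigma_log = fit$model$sigma_log,
               tau_mode_ps = td$summary$mode,
               residual_norm = fit$residual_norm,
               single_gamma_residual = fit$single_gamma_fit$residual_norm,
               converged = fit$converged)
        }
      }),
      stop_domain(sprintf("unknown pipeline stage: %s", stage)))
  }
  report <- structure(
    list(config = config, seed = seed, results = results,
         versions = list(
           package = as.character(utils::packageVersion("reorient")),
           r = paste(R.version$major, R.version$minor, sep = "."))),
    class = "run_report")
  if (!is.null(out_dir)) {
    yaml::write_yaml(list(seed = seed, stages = stages,
                          results = rapply(results, function(x) x,
                                           how = "replace")),
                     file.path(out_dir, "report.yaml"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("reorient run report (seed %d)\n", x$seed))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%s", names(r),
                              vapply(r, function(v)
                                paste(signif(unlist(v), 5), collapse = ","),
                                character(1L))),
                      collapse = ", ")))
  }
  invisible(x)
}
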