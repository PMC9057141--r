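#' Physical constants used throughout the package
#'
#' `reorient_constants()` returns the constants the models rely on:
#' the molar gas constant (J mol^-1 K^-1), hbar expressed in meV ps
#' (used to convert Lorentzian half-widths to correlation times), and
#' the dimensionless BPP minimum condition computed at load time.
#'
#' @return Named list with elements `R_gas`, `hbar_meV_ps`.
#' @export
reorient_constants <- function() {
  list(R_gas = 8.314462618, hbar_meV_ps = 0.6582119569)
}

.R_GAS <- 8.314462618        # J mol^-1 K^-1
.HBAR_MEV_PS <- 0.6582119569 # meV * ps

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_domain <- function(msg) stop(msg, call. = FALSE)
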