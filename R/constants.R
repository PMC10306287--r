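#' Physical constants and temperature conversion
#'
#' Thermodynamic calculations use the gas constant in kcal/(mol K) and the
#' Eyring prefactor k_B/h (CODATA values), with the transmission coefficient
#' fixed at 1. Temperatures are Kelvin internally; tabular interfaces and the
#' command line speak Celsius.
#'
#' @name topt-constants
NULL

# gas constant, kcal/(mol K)
.R_KCAL <- 1.987204e-3

# Boltzmann / Planck, 1/(K s): 1.380649e-23 / 6.62607015e-34
.KB_OVER_H <- 1.380649e-23 / 6.62607015e-34

.C_OFFSET <- 273.15

#' Convert temperatures between Celsius and Kelvin
#'
#' @param temp_C,temp_K temperatures in degrees Celsius / Kelvin.
#' @return numeric vector of converted temperatures.
#' @examples
#' to_kelvin(25)
#' to_celsius(313.15)
#' @export
to_kelvin <- function(temp_C) temp_C + .C_OFFSET

#' @rdname to_kelvin
#' @export
to_celsius <- function(temp_K) temp_K - .C_OFFSET

.check_temperature_K <- function(T_K) {
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be finite and positive (Kelvin)", call. = FALSE)
  }
  invisible(T_K)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All seeded generators in the package route through this helper so that a
# given (spec, seed) pair is bit-reproducible without clobbering the session.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
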