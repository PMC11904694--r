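#' @title Arrhenius rate parameters
#'
#' @description Container for the temperature dependence of an elementary-step
#' rate constant, `k(T) = A * exp(-Ea / (R * T))` with `T` in kelvin and
#' `R = 8.314` J/(mol K). Units of `A` (and hence of `k`) follow the step's
#' molecularity: 1/s for unimolecular steps, L/(mol s) for bimolecular steps.
#'
#' @param A pre-exponential factor (> 0), in the rate-constant's units.
#' @param Ea activation energy in J/mol (>= 0).
#' @return An object of class `arrheniusParams`.
#' @seealso [arrheniusFromRef()] for the reference-temperature
#'   parameterization used in fitting.
#' @export
arrheniusParams <- function(A, Ea) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0,
            is.numeric(Ea), length(Ea) == 1L, is.finite(Ea), Ea >= 0)
  structure(list(A = as.numeric(A), Ea = as.numeric(Ea)),
            class = "arrheniusParams")
}

#' Gas constant, J/(mol K)
#' @keywords internal
R_GAS <- 8.314

#' Build Arrhenius parameters from a reference-temperature rate constant
#'
#' Fitting uses `log10(k)` at a reference temperature plus `Ea` instead of
#' `(A, Ea)`: the two are strongly correlated while `k(Tref)` and `Ea` are
#' nearly orthogonal on data spanning a modest temperature window. `A` is
#' recovered algebraically as `kRef * exp(Ea / (R * Tref))`.
#'
#' @param kRef rate constant at `Tref` (> 0).
#' @param Ea activation energy, J/mol.
#' @param Tref reference temperature in kelvin (default 298.15).
#' @return An `arrheniusParams` object.
#' @export
arrheniusFromRef <- function(kRef, Ea, Tref = 298.15) {
  stopifnot(kRef > 0, Tref > 0)
  arrheniusParams(A = kRef * exp(Ea / (R_GAS * Tref)), Ea = Ea)
}

#' Rate constant at a given temperature
#'
#' @param params an `arrheniusParams` object.
#' @param T temperature(s) in kelvin, all > 0.
#' @return `A * exp(-Ea / (R * T))`, vectorized over `T`. Strictly increasing
#'   in `T` whenever `Ea > 0`.
#' @examples
#' p <- arrheniusParams(A = 5, Ea = 0)
#' rateConstant(p, 300)  # 5: with Ea = 0, k is temperature-independent
#' @export
rateConstant <- function(params, T) {
  stopifnot(inherits(params, "arrheniusParams"))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be finite and positive (kelvin)")
  params$A * exp(-params$Ea / (R_GAS * T))
}

#' @export
print.arrheniusParams <- function(x, ...) {
  cat(sprintf("Arrhenius: A = %.4g, Ea = %.4g kJ/mol (k(298.15 K) = %.4g)\n",
              x$A, x$Ea / 1000, rateConstant(x, 298.15)))
  invisible(x)
}

celsiusToKelvin <- function(x) x + 273.15
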