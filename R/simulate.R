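#' Experiment conditions for a batch simulation
#'
#' @param init named numeric vector of initial concentrations, mol/L
#'   (species absent from the vector start at 0).
#' @param tempC either a single temperature in degrees Celsius (isothermal
#'   batch, the default mode) or a data.frame with columns `time_min`,
#'   `temp_C` describing a piecewise-linear internal-temperature profile
#'   covering `[0, duration]`.
#' @param duration total duration in minutes (> 0).
#' @param id experiment identifier carried into time-course tables.
#' @return An object of class `conditions`.
#' @export
conditions <- function(init, tempC, duration, id = "exp") {
  stopifnot(is.numeric(init), !is.null(names(init)), all(init >= 0),
            is.numeric(duration), length(duration) == 1L, duration > 0)
  if (is.data.frame(tempC)) {
    stopifnot(all(c("time_min", "temp_C") %in% names(tempC)),
              nrow(tempC) >= 2L, !is.unsorted(tempC$time_min))
    if (min(tempC$time_min) > 0 || max(tempC$time_min) < duration)
      stop("temperature profile must cover [0, duration]")
    profile <- tempC[, c("time_min", "temp_C")]
  } else {
    stopifnot(is.numeric(tempC), length(tempC) == 1L)
    profile <- data.frame(time_min = c(0, duration), temp_C = c(tempC, tempC))
  }
  structure(list(init = init, profile = profile,
                 duration = as.numeric(duration), id = id),
            class = "conditions")
}

#' @export
print.conditions <- function(x, ...) {
  isoT <- isothermalTemp(x)
  cat(sprintf("Conditions '%s': %s, %.0f min\n", x$id,
              if (is.na(isoT)) "programmed T profile"
              else sprintf("%.1f degC", isoT), x$duration))
  cat("  init [mol/L]:",
      paste(sprintf("%s = %.4g", names(x$init), x$init), collapse = ", "),
      "\n")
  invisible(x)
}

# constant temperature in Celsius, or NA if the profile varies
isothermalTemp <- function(cond) {
  Tc <- cond$profile$temp_C
  if (max(Tc) - min(Tc) < 1e-12) Tc[1] else NA_real_
}

#' Temperature at given times under a conditions object
#'
#' @param cond a [conditions()] object.
#' @param timeMin times in minutes.
#' @return Temperatures in Celsius (linear interpolation, endpoints held).
#' @export
temperatureAt <- function(cond, timeMin) {
  stats::approx(cond$profile$time_min, cond$profile$temp_C, xout = timeMin,
                rule = 2)$y
}

#' Build the mass-action rate equations of a model
#'
#' Returns the ODE right-hand side as a plain R closure: each elementary
#' step contributes `k_j(T) * prod([reactant]^coefficient)` to the
#' derivative of every species it touches, with signed stoichiometry. The
#' simulator's default backend is a compiled equivalent; this closure is the
#' readable reference implementation and is used for cross-checking.
#'
#' @param model a [kineticModel()].
#' @return `function(conc, T)` mapping a named concentration vector (mol/L)
#'   and a temperature (kelvin) to the named derivative vector d(conc)/dt in
#'   mol/(L s).
#' @export
buildRateEquations <- function(model) {
  spNames <- model$species$name
  S <- length(spNames)
  ord <- stoichMatrices(model)$order
  net <- stoichMatrices(model)$net
  force(model)
  function(conc, T) {
    if (is.null(names(conc))) {
      if (length(conc) != S) stop("state length does not match species")
      y <- as.numeric(conc)
    } else {
      bad <- setdiff(names(conc), spNames)
      if (length(bad))
        stop("unknown species in state: ", paste(bad, collapse = ", "))
      y <- stats::setNames(numeric(S), spNames)
      y[names(conc)] <- conc
    }
    k <- stepRateConstants(model, T)
    ypos <- pmax(y, 0)
    rates <- k * apply(ord, 2, function(o) prod(ypos^o))
    stats::setNames(as.numeric(net %*% rates), spNames)
  }
}

# order (reactant-exponent) and net stoichiometry matrices, species x steps
stoichMatrices <- function(model) {
  spNames <- model$species$name
  S <- length(spNames)
  M <- length(model$steps)
  ord <- matrix(0, S, M, dimnames = list(spNames, names(model$steps)))
  net <- ord
  for (j in seq_len(M)) {
    s <- model$steps[[j]]
    ord[names(s$reactants), j] <- s$reactants
    net[names(s$reactants), j] <- net[names(s$reactants), j] - s$reactants
    net[names(s$products), j] <- net[names(s$products), j] + s$products
  }
  list(order = ord, net = net)
}

PARMS_LEN <- 1024L

compiledParms <- function(model, cond) {
  sm <- stoichMatrices(model)
  S <- nrow(sm$order); M <- ncol(sm$order)
  isoT <- isothermalTemp(cond)
  if (!is.na(isoT)) {
    tail <- stepRateConstants(model, celsiusToKelvin(isoT))
    head <- c(S, M, 0, 0)
  } else {
    A <- vapply(model$steps, function(s)
      if (isTRUE(s$zeroed)) 0 else s$params$A, numeric(1))
    Ea <- vapply(model$steps, function(s) s$params$Ea, numeric(1))
    tk <- cond$profile$time_min * 60
    TK <- celsiusToKelvin(cond$profile$temp_C)
    tail <- c(A, Ea, tk, TK)
    head <- c(S, M, 1, length(tk))
  }
  p <- c(head, as.numeric(sm$order), as.numeric(sm$net), tail)
  if (length(p) > PARMS_LEN)
    stop("model too large for the compiled backend (parameter block ",
         length(p), " > ", PARMS_LEN, ")")
  c(p, numeric(PARMS_LEN - length(p)))
}

#' Simulate a kinetic model and report conversion-yield time courses
#'
#' Integrates the mass-action ODE system with a stiff solver (`deSolve`
#' lsoda; the fast cation-capture steps make the borderline network stiff)
#' and reports the observable species as conversion yields, i.e. percent of
#' the initial limiting substrate (aniline, species `"1"`).
#'
#' Time is handled in minutes externally and seconds internally (rate
#' constants are per second). Yields are evaluated at exactly the requested
#' sample times.
#'
#' @param model a [kineticModel()].
#' @param cond a [conditions()] object.
#' @param times sample times in minutes, within `[0, duration]`.
#' @param rtol,atol solver tolerances (defaults 1e-8 relative, 1e-10 mol/L
#'   absolute).
#' @param backend `"compiled"` (default) or `"R"` (reference closure from
#'   [buildRateEquations()]; slower, used for cross-checks).
#' @param yieldRef concentration used as the 100% reference; defaults to the
#'   initial concentration of species `"1"` (or of the first reactant).
#' @return A `timeCourse` data.frame with columns `experiment_id`,
#'   `time_min`, `temp_C`, `species`, `yield_pct`, `source` (one row per
#'   observable species and time). The full concentration matrix (mol/L, all
#'   species, including t = 0) is attached as `attr(, "state")`.
#' @export
simulateTimeCourse <- function(model, cond, times,
                               rtol = 1e-8, atol = 1e-10,
                               backend = c("compiled", "R"),
                               yieldRef = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(model, "kineticModel"), inherits(cond, "conditions"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > cond$duration + 1e-9))
    stop("sample times must lie within [0, duration]")
  spNames <- model$species$name
  y0 <- stats::setNames(numeric(length(spNames)), spNames)
  known <- intersect(names(cond$init), spNames)
  y0[known] <- cond$init[known]
  if (is.null(yieldRef)) {
    ref <- if ("1" %in% spNames) "1" else
      spNames[model$species$role == "reactant"][1]
    if (is.na(ref) || y0[ref] <= 0)
      stop("cannot determine the 100% yield reference; pass yieldRef")
    yieldRef <- y0[[ref]]
  }
  tSec <- c(0, times * 60)
  tSec <- unique(tSec)

  solveWith <- function(method) {
    if (backend == "compiled") {
      deSolve::ode(y = y0, times = tSec, func = "kinwfi_derivs",
                   parms = compiledParms(model, cond),
                   dllname = "kinwfi", initfunc = "kinwfi_initmod",
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 1e5)
    } else {
      rhs <- buildRateEquations(model)
      isoT <- isothermalTemp(cond)
      Tof <- if (!is.na(isoT)) {
        TK <- celsiusToKelvin(isoT); function(t) TK
      } else function(t) celsiusToKelvin(temperatureAt(cond, t / 60))
      deSolve::ode(y = y0, times = tSec,
                   func = function(t, y, p) list(rhs(y, Tof(t))),
                   parms = NULL, method = method,
                   rtol = rtol, atol = atol, maxsteps = 1e5)
    }
  }
  solveFailed <- function(out) {
    istate <- attr(out, "istate")
    (!is.null(istate) && istate[1] < 0) || anyNA(out)
  }
  out <- solveWith("lsoda")
  if (solveFailed(out))  # lsoda can stall on borderline-stiff parameter
    out <- suppressWarnings(solveWith("bdf"))   # sets; plain BDF is sturdier
  if (solveFailed(out))
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         ") for experiment '", cond$id, "'; try looser tolerances or ",
         "check rate parameters")
  state <- out[, spNames, drop = FALSE]
  worst <- min(state)
  if (worst < -1e-4 * max(abs(y0), 1e-12))
    stop("integration produced significantly negative concentrations (",
         format(worst), "); the system may be ill-posed")
  state[state < 0] <- 0
  rownames(state) <- NULL

  obs <- model$species$name[model$species$observable]
  keep <- match(times * 60, out[, "time"])
  tempC <- temperatureAt(cond, times)
  tc <- do.call(rbind, lapply(obs, function(sp)
    data.frame(experiment_id = cond$id, time_min = times, temp_C = tempC,
               species = sp,
               yield_pct = 100 * state[keep, sp] / yieldRef,
               source = "simulated", stringsAsFactors = FALSE)))
  rownames(tc) <- NULL
  class(tc) <- c("timeCourse", "data.frame")
  attr(tc, "state") <- state
  attr(tc, "stateTimesMin") <- out[, "time"] / 60
  attr(tc, "yieldRef") <- yieldRef
  tc
}

#' Check a model's conservation laws on a simulated state matrix
#'
#' @param model a [kineticModel()] with conservation laws.
#' @param state concentration matrix (rows = times, columns = species), e.g.
#'   `attr(simulateTimeCourse(...), "state")`.
#' @return Named vector of maximum relative drifts of each conserved total
#'   from its initial value.
#' @export
conservationDrift <- function(model, state) {
  if (!length(model$conservation)) return(numeric(0))
  vapply(model$conservation, function(coefs) {
    tot <- as.numeric(state[, names(coefs), drop = FALSE] %*% coefs)
    if (abs(tot[1]) < .Machine$double.eps) return(max(abs(tot)))
    max(abs(tot - tot[1]) / abs(tot[1]))
  }, numeric(1))
}

#' Instantaneous pathway rates and SN1/SN2 rate ratio
#'
#' For a borderline model, compares the flux entering each substitution
#' pathway at a given state: the SN1 rate is the ionization flux
#' `k_ion * [BnBr]` and the SN2 rate the concerted monobenzylation flux
#' `k_sn2 * [1] * [BnBr]`. The two rate constants have different units
#' (1/s vs L/(mol s)); comparing fluxes at a concrete state, as done here,
#' is what makes the pathway commitment well defined.
#'
#' @param model a [kineticModel()] containing steps labelled `"ion"` and
#'   `"sn2.mono"`.
#' @param state named concentration vector, mol/L.
#' @param T temperature in kelvin.
#' @return List with `sn1`, `sn2` (mol/(L s)), `ratio` (= sn1/sn2) and
#'   `defined` (FALSE when both rates are 0, in which case `ratio` is NA
#'   rather than NaN).
#' @export
pathwayRates <- function(model, state, T) {
  need <- c("ion", "sn2.mono")
  if (!all(need %in% names(model$steps)))
    stop("model must contain both pathway branches (steps 'ion' and ",
         "'sn2.mono')")
  k <- stepRateConstants(model, T)
  conc <- function(nm) if (nm %in% names(state)) max(state[[nm]], 0) else 0
  sn1 <- k[["ion"]] * conc("BnBr")
  sn2 <- k[["sn2.mono"]] * conc("1") * conc("BnBr")
  if (sn1 == 0 && sn2 == 0)
    return(list(sn1 = 0, sn2 = 0, ratio = NA_real_, defined = FALSE))
  list(sn1 = sn1, sn2 = sn2,
       ratio = if (sn2 > 0) sn1 / sn2 else Inf, defined = TRUE)
}

#' SN1/SN2 pathway ratio along a simulated reaction, by temperature
#'
#' Simulates the model under the given stoichiometry at each temperature and
#' evaluates [pathwayRates()] at a fixed time after the start of reaction
#' (default 10 min), yielding the temperature-dependent pathway-commitment
#' ratio.
#'
#' @param model a borderline [kineticModel()].
#' @param init named initial concentrations, mol/L.
#' @param tempC vector of temperatures, Celsius.
#' @param atTime evaluation time, minutes.
#' @param ... passed to [simulateTimeCourse()].
#' @return data.frame with columns `temp_C`, `rate_sn1`, `rate_sn2`,
#'   `ratio`.
#' @export
pathwayRatioByTemperature <- function(model, init, tempC, atTime = 10, ...) {
  rows <- lapply(tempC, function(Tc) {
    cond <- conditions(init, Tc, duration = atTime,
                       id = sprintf("ratio_%gC", Tc))
    tc <- simulateTimeCourse(model, cond, times = atTime, ...)
    state <- attr(tc, "state")
    st <- stats::setNames(as.numeric(state[nrow(state), ]),
                          colnames(state))
    pr <- pathwayRates(model, as.list(st), celsiusToKelvin(Tc))
    data.frame(temp_C = Tc, rate_sn1 = pr$sn1, rate_sn2 = pr$sn2,
               ratio = pr$ratio)
  })
  do.call(rbind, rows)
}
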