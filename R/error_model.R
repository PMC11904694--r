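#' Weighted relative-error model parameters
#'
#' The relative experimental error of a conversion yield is modeled as an
#' exponential-decay ("Stirling growth") curve of the yield `x` (fraction,
#' 1.0 = full conversion):
#'
#'   `f(x) = a + (b/k) * (exp(k*x) - 1)`,   with `b < 0`, `k < 0`.
#'
#' `f` starts at `a` at zero conversion, decays exponentially and converges
#' to a plateau of `a - b/k`: low-yield (early) data carry a large relative
#' error, high-yield data a small one. The defaults `a = 1, b = -9, k = -10`
#' describe a 100% relative error at zero conversion decaying to a 10%
#' plateau.
#'
#' @param a relative error at zero conversion (fraction, in (0, 1.5]).
#' @param b initial decay-slope parameter (< 0).
#' @param k exponential decay rate (< 0).
#' @param floor minimum absolute half-width of the error band, as a yield
#'   fraction (default 0.005, i.e. half a percentage point, representing the
#'   analytical limit of quantification; keeps the band non-degenerate at
#'   zero simulated yield).
#' @return An object of class `errorModelParams`.
#' @export
errorModelParams <- function(a = 1, b = -9, k = -10, floor = 0.005) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), is.numeric(k),
            is.numeric(floor), floor >= 0)
  if (b >= 0 || k >= 0)
    stop("b and k must be negative (decaying relative error)")
  plateau <- a - b / k
  if (plateau <= 0)
    stop("plateau a - b/k must stay positive (relative error never vanishes)")
  structure(list(a = as.numeric(a), b = as.numeric(b), k = as.numeric(k),
                 floor = as.numeric(floor)),
            class = "errorModelParams")
}

#' @export
print.errorModelParams <- function(x, ...) {
  cat(sprintf(
    "Weighted error curve: a = %.4g, b = %.4g, k = %.4g (plateau %.3g%%), floor %.2g\n",
    x$a, x$b, x$k, 100 * (x$a - x$b / x$k), x$floor))
  invisible(x)
}

# raw curve, usable during calibration before sign constraints are settled
stirlingCurve <- function(x, a, b, k) {
  if (abs(k) < 1e-12) a + b * x else a + (b / k) * expm1(k * x)
}

#' Weighted relative error at a simulated yield
#'
#' @param x simulated yield fraction(s), >= 0 (1.0 = full conversion).
#' @param params an [errorModelParams()] object.
#' @return Relative error fraction(s) `f(x)`; `f(0) = a`, plateau `a - b/k`.
#' @examples
#' p <- errorModelParams()         # a = 1, b = -9, k = -10
#' stirlingError(0, p)             # 1.00: 100% relative error at x = 0
#' stirlingError(1, p)             # ~0.10: the 10% plateau
#' @export
stirlingError <- function(x, params) {
  stopifnot(inherits(params, "errorModelParams"))
  if (any(x < 0)) stop("yield fraction must be >= 0")
  stirlingCurve(x, params$a, params$b, params$k)
}

#' Assumed relative-error table
#'
#' A small table of (simulated yield, assumed relative error) anchor points
#' from which the continuous error curve is calibrated; the classic example
#' assumes ~50% relative error near 10% yield and ~10% at 50% yield and
#' above.
#'
#' @param yield yield fractions in `[0, 1]`, strictly increasing.
#' @param relError assumed relative-error fractions in `(0, 1.5]`.
#' @return data.frame of class `assumedErrorTable`.
#' @export
assumedErrorTable <- function(yield, relError) {
  stopifnot(length(yield) == length(relError))
  if (any(yield < 0) || any(yield > 1) || is.unsorted(yield, strictly = TRUE))
    stop("yield must be strictly increasing within [0, 1]")
  if (any(relError <= 0) || any(relError > 1.5))
    stop("relative errors must lie in (0, 1.5]")
  structure(data.frame(yield = yield, relError = relError),
            class = c("assumedErrorTable", "data.frame"))
}

#' The default assumed-error anchor points
#'
#' Yield 0 -> 100% (a temporary anchor for the fit), 10% -> 50%,
#' 30% -> 15%, 50% -> 10%, 100% -> 10%.
#' @return An [assumedErrorTable()].
#' @export
defaultAssumedErrors <- function() {
  assumedErrorTable(yield = c(0, 0.1, 0.3, 0.5, 1.0),
                    relError = c(1.00, 0.50, 0.15, 0.10, 0.10))
}

#' Calibrate the weighted-error curve from an assumed-error table
#'
#' Least-squares fit of `(a, b, k)` under the constraints `a` in (0, 1.5],
#' `b, k` in [-100, 0). Five deterministic starting points guard against
#' local minima of the exponential fit. Refitting the curve on its own
#' values recovers the parameters (self-consistency).
#'
#' @param table an [assumedErrorTable()] (or data.frame with columns
#'   `yield`, `relError`), at least 3 rows.
#' @param floor band floor passed through to the result.
#' @return An [errorModelParams()] object with the residuals of the fit in
#'   `attr(, "residuals")` and the summed squared residual in
#'   `attr(, "ssr")`.
#' @export
calibrateErrorModel <- function(table, floor = 0.005) {
  stopifnot(all(c("yield", "relError") %in% names(table)))
  x <- table$yield; y <- table$relError
  if (length(x) < 3)
    stop("calibration needs at least 3 rows; (a, b, k) is underdetermined")
  lower <- c(a = 1e-6, b = -100, k = -100)
  upper <- c(a = 1.5, b = -1e-8, k = -1e-8)
  resid <- function(p) stirlingCurve(x, p[1], p[2], p[3]) - y
  starts <- list(c(y[1], -1, -2), c(y[1], -9, -10), c(y[1], -20, -20),
                 c(y[1], -5, -30), c(1, -50, -50))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("calibration failed from every starting point")
  if (best$info == 0 || best$info == 9)
    warning("error-curve calibration did not fully converge; ",
            "returning the best candidate (info = ", best$info, ")")
  p <- best$par
  out <- errorModelParams(a = p[[1]], b = min(p[[2]], -1e-8),
                          k = min(p[[3]], -1e-8), floor = floor)
  attr(out, "residuals") <- resid(unlist(p))
  attr(out, "ssr") <- best$deviance
  out
}

#' Band half-width at a simulated yield
#'
#' @param Ys simulated yield fraction(s).
#' @param params an [errorModelParams()].
#' @return `max(f(Ys) * Ys, floor)`, the half-width of the weighted error
#'   band, as a yield fraction.
#' @export
bandHalfWidth <- function(Ys, params) {
  pmax(stirlingError(Ys, params) * Ys, params$floor)
}

#' Weighted error band centered on the simulated curve
#'
#' The continuous error range used for model evaluation is centered on the
#' *simulated* yield (model uncertainty is what is being minimized), with a
#' relative half-width from the Stirling curve: wide at low yield, narrow
#' (plateau) near full conversion.
#'
#' @param Ys simulated yield fraction(s), >= 0.
#' @param params an [errorModelParams()].
#' @return data.frame with columns `lower`, `upper` (lower clipped at 0).
#' @examples
#' p <- errorModelParams()
#' errorBand(0.5, p)  # about 0.447 - 0.553: ~10% relative error at 50% yield
#' @export
errorBand <- function(Ys, params) {
  w <- bandHalfWidth(Ys, params)
  data.frame(lower = pmax(Ys - w, 0), upper = Ys + w)
}

#' Absolute deviation between simulated and experimental yield
#'
#' @param Ys,Ye simulated and experimental yields (same scale).
#' @return `|Ys - Ye|`.
#' @export
absoluteError <- function(Ys, Ye) abs(Ys - Ye)

# core WFI on matched fraction-scale vectors
wfiCore <- function(Ys, Ye, params) {
  w <- bandHalfWidth(Ys, params)
  mean(absoluteError(Ys, Ye) / w)
}

matchSeries <- function(sim, obs) {
  need <- c("experiment_id", "time_min", "species", "yield_pct")
  stopifnot(all(need %in% names(sim)), all(need %in% names(obs)))
  key <- function(d) paste(d$experiment_id, d$species,
                           format(d$time_min, digits = 12))
  i <- match(key(obs), key(sim))
  if (anyNA(i))
    stop("experimental points have no simulated counterpart at the same ",
         "time; simulate at the experimental sample times first")
  data.frame(experiment_id = obs$experiment_id, species = obs$species,
             time_min = obs$time_min,
             Ys = sim$yield_pct[i] / 100, Ye = obs$yield_pct / 100,
             stringsAsFactors = FALSE)
}

#' Weighted fitting index (WFI) of a simulated vs experimental series
#'
#' The WFI averages, over the `n` matched data points, the absolute
#' simulated-vs-experimental deviation divided by the weighted band
#' half-width at the simulated yield:
#'
#'   `WFI = (1/n) * sum( |Ys_i - Ye_i| / max(f(Ys_i) * Ys_i, floor) )`
#'
#' It is 0 when every point sits exactly on the simulation and 1 when the
#' average distance equals the band half-width; WFI < 1 means the data lie,
#' on average, within the weighted error range. The t = 0 point is excluded
#' by default (both series vanish there and the band degenerates to the
#' floor).
#'
#' @param sim,obs `timeCourse` data.frames (columns `experiment_id`,
#'   `time_min`, `species`, `yield_pct`); `sim` must contain every
#'   (experiment, species, time) present in `obs`.
#' @param params an [errorModelParams()].
#' @param includeTimeZero keep t = 0 points (default FALSE).
#' @return A single numeric WFI value across all matched points.
#' @export
wfi <- function(sim, obs, params = errorModelParams(),
                includeTimeZero = FALSE) {
  if (!nrow(obs)) stop("empty experimental series")
  if (!includeTimeZero) obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (!nrow(obs)) stop("no experimental points left after dropping t = 0")
  m <- matchSeries(sim, obs)
  wfiCore(m$Ys, m$Ye, params)
}

#' Per-species, per-experiment WFI report
#'
#' The tabular layout used throughout model evaluation: one WFI per
#' (experiment, species) series plus the arithmetic mean across species per
#' experiment. Species present in the data but absent from the simulation
#' are reported as `NA` and excluded from the averages with a warning.
#'
#' @inheritParams wfi
#' @return An object of class `wfiReport`: list with `perSeries`
#'   (experiment_id, species, n, wfi) and `perExperiment` (experiment_id,
#'   ave, nSpecies) data.frames.
#' @export
wfiReport <- function(sim, obs, params = errorModelParams(),
                      includeTimeZero = FALSE) {
  if (!includeTimeZero) obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (!nrow(obs)) stop("empty experimental series")
  simSpecies <- unique(sim$species)
  combos <- unique(obs[, c("experiment_id", "species")])
  combos <- combos[order(combos$experiment_id, combos$species), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- obs[obs$experiment_id == combos$experiment_id[i] &
                 obs$species == combos$species[i], , drop = FALSE]
    if (!combos$species[i] %in% simSpecies) {
      warning("species '", combos$species[i],
              "' has no simulated series; excluded from averages")
      return(data.frame(experiment_id = combos$experiment_id[i],
                        species = combos$species[i], n = nrow(sub),
                        wfi = NA_real_))
    }
    m <- matchSeries(sim, sub)
    data.frame(experiment_id = combos$experiment_id[i],
               species = combos$species[i], n = nrow(m),
               wfi = wfiCore(m$Ys, m$Ye, params))
  })
  perSeries <- do.call(rbind, rows)
  ave <- vapply(split(perSeries, perSeries$experiment_id), function(d)
    mean(d$wfi, na.rm = TRUE), numeric(1))
  nsp <- vapply(split(perSeries, perSeries$experiment_id), function(d)
    sum(!is.na(d$wfi)), numeric(1))
  perExperiment <- data.frame(experiment_id = names(ave), ave = unname(ave),
                              nSpecies = unname(nsp))
  structure(list(perSeries = perSeries, perExperiment = perExperiment),
            class = "wfiReport")
}

#' @export
print.wfiReport <- function(x, digits = 2, ...) {
  wide <- stats::reshape(
    x$perSeries[, c("experiment_id", "species", "wfi")],
    idvar = "experiment_id", timevar = "species", direction = "wide")
  names(wide) <- sub("^wfi\\.", "", names(wide))
  wide$Ave. <- x$perExperiment$ave[match(wide$experiment_id,
                                         x$perExperiment$experiment_id)]
  rownames(wide) <- NULL
  cat("WFI values per species series\n")
  print(format(wide, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Pooled average WFI of a report
#'
#' @param report a [wfiReport()].
#' @return Mean of the per-experiment averages.
#' @export
pooledWFI <- function(report) {
  stopifnot(inherits(report, "wfiReport"))
  mean(report$perExperiment$ave)
}
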