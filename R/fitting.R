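#' Specification of a kinetic-parameter fit
#'
#' @param model starting [kineticModel()]; steps not listed in `free` keep
#'   their current parameters fixed (e.g. the fast cation-capture reference
#'   constant, of which only the mono/di capture ratio is practically
#'   identifiable).
#' @param data a `timeCourse` data.frame of experimental points.
#' @param conds named list of [conditions()] covering every
#'   `experiment_id` in `data`.
#' @param free character vector of free parameter names in the
#'   `log10k.<step>` / `Ea.<step>` notation of [getModelParams()].
#' @param errorParams [errorModelParams()] used for the residual weights.
#' @param objective `"wls"` (weighted least squares: residuals
#'   `(Ys - Ye)/w`, i.e. weights are the inverse squared band half-widths)
#'   or `"wfi"` (minimizes the summed band-relative absolute deviation,
#'   proportional to the WFI, via square-root-transformed residuals).
#' @param trainingIds experiment ids to fit on (default: all in `data`).
#' @param nStarts number of deterministic multi-starts: a ladder of six
#'   chemically anchored points plus low-discrepancy filler spanning the
#'   bounds (log-spaced in the rate constants).
#' @param refine number of best-screened starts to optimize fully (seeded
#'   starts are always optimized in addition).
#' @param lower,upper optional named bound overrides.
#' @param start optional named starting values (always included as an extra
#'   start).
#' @return Object of class `fitSpec`.
#' @export
fitSpec <- function(model, data, conds, free,
                    errorParams = errorModelParams(),
                    objective = c("wls", "wfi"),
                    trainingIds = NULL, nStarts = 8, refine = 3,
                    lower = NULL, upper = NULL, start = NULL) {
  objective <- match.arg(objective)
  stopifnot(inherits(model, "kineticModel"), is.data.frame(data),
            length(free) >= 1)
  ids <- unique(data$experiment_id)
  if (is.null(trainingIds)) trainingIds <- ids
  if (!all(trainingIds %in% ids)) stop("trainingIds not present in data")
  if (!all(trainingIds %in% names(conds)))
    stop("conditions missing for: ",
         paste(setdiff(trainingIds, names(conds)), collapse = ", "))
  known <- names(getModelParams(model))
  if (!all(free %in% known))
    stop("unknown free parameters: ",
         paste(setdiff(free, known), collapse = ", "))
  structure(list(model = model, data = data, conds = conds, free = free,
                 errorParams = errorParams, objective = objective,
                 trainingIds = trainingIds, nStarts = nStarts,
                 refine = max(1L, min(refine, nStarts)),
                 lower = lower, upper = upper, start = start),
            class = "fitSpec")
}

defaultBounds <- function(free) {
  lower <- ifelse(startsWith(free, "log10k."), -9, 1e3)
  upper <- ifelse(startsWith(free, "log10k."), 3, 2e5)
  list(lower = stats::setNames(lower, free),
       upper = stats::setNames(upper, free))
}

# is a free log10k dimension attached to a step that consumes a transient
# intermediate? such steps (e.g. cation capture) are fast by construction
# and their rate constants should start high, not on the slow ladder
fastDims <- function(model, free) {
  vapply(free, function(nm) {
    if (!startsWith(nm, "log10k.")) return(FALSE)
    lab <- sub("^log10k\\.", "", nm)
    s <- model$steps[[lab]]
    roles <- model$species$role[match(names(s$reactants),
                                      model$species$name)]
    any(roles == "intermediate")
  }, logical(1))
}

# deterministic multi-start construction:
#   - a "ladder" of chemically plausible anchors: every slow-step log10k at
#     a common level in -6..-1, intermediate-consuming steps at log10k = 1,
#     all free Ea at a typical 70 kJ/mol
#   - low-discrepancy (Halton) filler points spanning the full bounds
#   - optional seeds carried over from fits of simpler (single-pathway)
#     candidate models, plus a variant with the seeded slow rate constants
#     halved, since pathways that previously carried all the flux now share
#     it
buildStarts <- function(spec, lower, upper, seedFits) {
  free <- spec$free
  fast <- fastDims(spec$model, free)
  kdim <- startsWith(free, "log10k.")
  anchor <- function(k0) {
    st <- stats::setNames(numeric(length(free)), free)
    st[kdim] <- k0
    st[fast] <- 1
    st[!kdim] <- 7e4
    pmin(pmax(st, lower), upper)
  }
  starts <- lapply(seq(-6, -1), anchor)
  nHalton <- max(0L, spec$nStarts - length(starts))
  if (nHalton > 0) {
    h <- haltonPoints(nHalton, length(free))
    starts <- c(starts, lapply(seq_len(nHalton), function(i)
      lower + h[i, ] * (upper - lower)))
  }
  seeded <- rep(FALSE, length(starts))
  addSeed <- function(base) {
    att <- base
    att[kdim & !fast] <- att[kdim & !fast] - log10(2)
    starts <<- c(starts, list(pmin(pmax(base, lower), upper),
                              pmin(pmax(att, lower), upper)))
    seeded <<- c(seeded, TRUE, TRUE)
  }
  if (length(seedFits)) {
    merged <- anchor(-4)
    for (sf in seedFits) {
      base <- anchor(-4)
      shared <- intersect(names(sf$par), free)
      base[shared] <- sf$par[shared]
      merged[shared] <- sf$par[shared]
      addSeed(base)
    }
    # all priors merged: a competing-pathway model assembled from every
    # single-pathway solution at once
    if (length(seedFits) > 1) addSeed(merged)
  }
  if (!is.null(spec$start)) {
    s0 <- unlist(spec$start)[free]
    if (anyNA(s0)) stop("start must name every free parameter")
    starts <- c(list(pmin(pmax(s0, lower), upper)), starts)
    seeded <- c(TRUE, seeded)
  }
  attr(starts, "seeded") <- seeded
  starts
}

# radical-inverse (Halton) low-discrepancy points: deterministic multi-start
# grid, log-spaced in the rate-constant dimensions
haltonPoints <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (d > length(primes)) stop("too many free parameters for the start grid")
  radInv <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  m <- vapply(seq_len(d), function(j)
    vapply(seq_len(n) + 3, radInv, numeric(1), base = primes[j]),
    numeric(n))
  matrix(m, nrow = n, ncol = d)
}

# residual vector across training experiments; one entry per data point
# (t = 0 excluded, matching the WFI convention)
makeResidFun <- function(spec) {
  obs <- spec$data[spec$data$experiment_id %in% spec$trainingIds &
                     spec$data$time_min > 0, , drop = FALSE]
  if (!nrow(obs)) stop("no usable training points (all at t = 0?)")
  byExp <- split(obs, obs$experiment_id)
  ep <- spec$errorParams
  sqrtTrans <- spec$objective == "wfi"
  nPoints <- nrow(obs)
  function(theta) {
    names(theta) <- spec$free
    m <- setModelParams(spec$model, theta)
    res <- lapply(names(byExp), function(id) {
      d <- byExp[[id]]
      sim <- try(suppressWarnings(
        simulateTimeCourse(m, spec$conds[[id]],
                           sort(unique(d$time_min)))),
        silent = TRUE)
      if (inherits(sim, "try-error")) return(rep(1e4, nrow(d)))
      mm <- matchSeries(sim, d)
      r <- (mm$Ys - mm$Ye) / bandHalfWidth(mm$Ys, ep)
      r[!is.finite(r)] <- 1e4
      r
    })
    r <- unlist(res, use.names = FALSE)
    if (sqrtTrans) r <- sign(r) * sqrt(abs(r))
    r
  }
}

#' Fit kinetic parameters to multi-experiment time courses
#'
#' Bounded Levenberg-Marquardt least squares (via `minpack.lm`) over all
#' training experiments jointly, from a deterministic set of multi-start
#' points: a ladder of chemically plausible anchors (common `log10k` level
#' for the slow steps, fast starts for intermediate-consuming steps, a
#' typical 70 kJ/mol activation energy), low-discrepancy filler points over
#' the bounds, and optional seeds from simpler candidate fits. All starts
#' are screened by objective value and the best few (plus every seeded
#' start) optimized fully. Residuals are band-weighted per point;
#' experiments are not weighted against each other beyond their point
#' counts. Fully deterministic: identical specs give identical results.
#'
#' When any `Ea.*` parameter is free the training experiments must span at
#' least two distinct temperatures, otherwise the activation energy is
#' unidentifiable and an error is raised.
#'
#' @param spec a [fitSpec()].
#' @param seedFits optional list of `kinFit` results from simpler candidate
#'   models (e.g. the single-pathway mechanisms); their shared parameters
#'   seed additional starts for the composite model, the way a practitioner
#'   builds a competing-pathway model from the single-mechanism fits.
#' @return Object of class `kinFit`: `par` (best parameters), `model` (the
#'   model with best parameters applied), `ssr` (objective at the optimum),
#'   `starts` (screening/optimization trace), `converged`, `spec`,
#'   `parHash` (fingerprint used by the no-refit guarantee of
#'   [extrapolabilityCheck()]), and `curvature` (local standard-error
#'   estimates from the Jacobian at the optimum; a local approximation
#'   only, not a model-adequacy statement).
#' @export
fitKinetics <- function(spec, seedFits = NULL) {
  stopifnot(inherits(spec, "fitSpec"))
  if (any(startsWith(spec$free, "Ea."))) {
    temps <- unique(round(unlist(lapply(
      spec$conds[spec$trainingIds],
      function(cd) cd$profile$temp_C)), 6))
    if (length(temps) < 2)
      stop("activation energies are unidentifiable from a single ",
           "temperature; provide experiments at >= 2 temperatures or fix ",
           "the Ea parameters")
  }
  b <- defaultBounds(spec$free)
  lower <- b$lower; upper <- b$upper
  if (!is.null(spec$lower)) lower[names(spec$lower)] <- spec$lower
  if (!is.null(spec$upper)) upper[names(spec$upper)] <- spec$upper
  residFun <- makeResidFun(spec)

  starts <- buildStarts(spec, lower, upper, seedFits)
  # refine the best-screened starts; user-given and seeded starts are
  # always polished regardless of their screening rank
  screen <- vapply(starts, function(s) sum(residFun(s)^2), numeric(1))
  ord <- order(screen)
  pick <- union(which(attr(starts, "seeded")),
                ord[seq_len(min(spec$refine, length(starts)))])

  # epsfcn keeps the finite-difference Jacobian step above the ODE
  # solver's noise floor (rtol 1e-8); the machine-eps default makes the
  # numeric gradient pure integration noise
  runs <- lapply(pick, function(i) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[i]], lower = lower, upper = upper, fn = residFun,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13, epsfcn = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("optimization failed from every start")
  runs <- runs[ok]; pick <- pick[ok]
  dev <- vapply(runs, `[[`, numeric(1), "deviance")
  best <- runs[[which.min(dev)]]
  par <- stats::setNames(unlist(best$par), spec$free)

  atLower <- abs(par - lower) < 1e-8
  atUpper <- abs(par - upper) < 1e-8
  if (any(atLower | atUpper))
    warning("parameters at bounds: ",
            paste(spec$free[atLower | atUpper], collapse = ", "))

  curv <- tryCatch({
    covm <- solve(best$hessian) * best$deviance /
      max(1, length(best$fvec) - length(par))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(par)))

  startsTab <- data.frame(
    start = seq_along(starts), screenedSSR = screen,
    optimized = seq_along(starts) %in% pick,
    finalSSR = NA_real_)
  startsTab$finalSSR[pick] <- dev

  structure(list(
    par = par, model = setModelParams(spec$model, par),
    ssr = best$deviance, starts = startsTab,
    converged = best$info %in% 1:4, info = best$info,
    curvature = stats::setNames(curv, spec$free),
    spec = spec, parHash = paramHash(par)),
    class = "kinFit")
}

paramHash <- function(par)
  paste(names(par), format(par, digits = 17), sep = "=", collapse = ";")

#' @export
print.kinFit <- function(x, ...) {
  cat(sprintf("Kinetic fit of model '%s' (%s objective): SSR = %.6g%s\n",
              x$spec$model$name, x$spec$objective, x$ssr,
              if (x$converged) "" else "  [NOT converged]"))
  est <- data.frame(estimate = x$par, local.se = x$curvature)
  print(est, digits = 4)
  cat("(local.se: curvature-based local approximation only)\n")
  invisible(x)
}

# simulate the fitted model at the sample times of the given experiments
simulateAtData <- function(fit, data, conds) {
  ids <- unique(data$experiment_id)
  sims <- lapply(ids, function(id) {
    d <- data[data$experiment_id == id, ]
    simulateTimeCourse(fit$model, conds[[id]],
                       sort(unique(d$time_min[d$time_min > 0])))
  })
  out <- do.call(rbind, lapply(sims, as.data.frame))
  class(out) <- c("timeCourse", "data.frame")
  out
}

#' Self-reproducibility WFI report of a fit
#'
#' Simulates each training experiment at its own sample times with the
#' fitted parameters and scores the fit with the per-species WFI table:
#' how well the model reproduces the data it was trained on
#' (interpolation).
#'
#' @param fit a [fitKinetics()] result.
#' @return A [wfiReport()].
#' @export
selfReproducibility <- function(fit) {
  stopifnot(inherits(fit, "kinFit"))
  obs <- fit$spec$data[fit$spec$data$experiment_id %in%
                         fit$spec$trainingIds, ]
  sim <- simulateAtData(fit, obs, fit$spec$conds)
  wfiReport(sim, obs, fit$spec$errorParams)
}

#' Extrapolability WFI report of a fit on held-out conditions
#'
#' Predicts held-out experiments (typically outside the trained temperature
#' and stoichiometry range) with the training-fitted parameters and no
#' refitting — the package's primary model-validity check: a mechanistically
#' right model extrapolates, an overfitted one does not. The function
#' verifies that the fit's parameters are untouched via their fingerprint.
#'
#' @param fit a [fitKinetics()] result.
#' @param data held-out `timeCourse` data.
#' @param conds named list of [conditions()] for the held-out ids.
#' @return A [wfiReport()].
#' @export
extrapolabilityCheck <- function(fit, data, conds) {
  stopifnot(inherits(fit, "kinFit"))
  if (!identical(paramHash(fit$par), fit$parHash))
    stop("fit parameters were modified after fitting; refusing to report ",
         "extrapolability")
  sim <- simulateAtData(fit, data, conds)
  wfiReport(sim, data, fit$spec$errorParams)
}

#' Fit and rank candidate mechanisms
#'
#' Fits each candidate spec on the shared training data, and tabulates the
#' pooled self-reproducibility WFI (mean over training experiments of the
#' per-experiment species averages) and, when held-out data are given, the
#' pooled extrapolation WFI. Candidates are fitted in order of increasing
#' free-parameter count and each fit seeds the starts of the more complex
#' candidates after it (see [fitKinetics()]), so a competing-pathway model
#' starts from the single-pathway solutions. Candidates are ranked by
#' pooled self-reproducibility WFI; candidates whose optimization fails are
#' flagged and excluded from the ranking.
#'
#' @param specs named list of [fitSpec()] objects sharing the experiments.
#' @param heldOutData,heldOutConds optional held-out data and conditions.
#' @return Object of class `modelComparison`: a data.frame with one row per
#'   candidate (`model`, `nFree`, `ssr`, `trainWFI`, `extrapWFI`,
#'   `converged`, `rank`), with the fits in `attr(, "fits")`.
#' @export
compareModels <- function(specs, heldOutData = NULL, heldOutConds = NULL) {
  stopifnot(length(specs) >= 1, !is.null(names(specs)))
  fitOrder <- names(specs)[order(vapply(specs, function(s)
    length(s$free), integer(1)))]
  fits <- list()
  for (nm in fitOrder) {
    seeds <- Filter(function(f) inherits(f, "kinFit"), fits)
    fits[[nm]] <- tryCatch(fitKinetics(specs[[nm]], seedFits = seeds),
                           error = function(e) e)
  }
  fits <- fits[names(specs)]
  rows <- lapply(names(specs), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "error"))
      return(data.frame(model = nm, nFree = length(specs[[nm]]$free),
                        ssr = NA_real_, trainWFI = NA_real_,
                        extrapWFI = NA_real_, converged = FALSE))
    tw <- pooledWFI(selfReproducibility(f))
    ew <- if (!is.null(heldOutData))
      pooledWFI(extrapolabilityCheck(f, heldOutData, heldOutConds))
    else NA_real_
    data.frame(model = nm, nFree = length(f$par), ssr = f$ssr,
               trainWFI = tw, extrapWFI = ew, converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  tab$rank <- NA_integer_
  okRank <- !is.na(tab$trainWFI)
  tab$rank[okRank] <- rank(tab$trainWFI[okRank], ties.method = "first")
  tab <- tab[order(is.na(tab$trainWFI), tab$trainWFI), ]
  rownames(tab) <- NULL
  structure(tab, class = c("modelComparison", "data.frame"), fits = fits)
}
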