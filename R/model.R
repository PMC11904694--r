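#' Define a chemical species
#'
#' @param name short identifier, unique within a model (e.g. `"1"` for
#'   aniline, `"2"` for N-benzylaniline, `"di-2"` for N,N-dibenzylaniline).
#' @param role one of `"reactant"`, `"intermediate"`, `"product"`,
#'   `"reagent"`.
#' @param observable is the species tracked analytically (HPLC)? Observable
#'   species are the ones reported as conversion yields and scored by the WFI.
#' @return A one-row data.frame with columns `name`, `role`, `observable`.
#' @export
species <- function(name, role = c("reactant", "intermediate", "product",
                                   "reagent"),
                    observable = TRUE) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(observable), length(observable) == 1L)
  data.frame(name = name, role = role, observable = observable,
             stringsAsFactors = FALSE)
}

#' Define an elementary step
#'
#' Elementary steps obey mass action with integer stoichiometry: the rate is
#' `k(T) * prod([reactant]^coefficient)`. Only uni- and bimolecular steps are
#' allowed; fractional orders are excluded by construction, since an
#' elementary mechanism implies integer orders in every species.
#'
#' @param reactants named integer vector, species -> stoichiometric
#'   coefficient (positive integers; total molecularity 1 or 2).
#' @param products named integer vector of product coefficients.
#' @param params an [arrheniusParams()] object for the step's rate constant.
#' @param label short unique identifier used to address the step's parameters
#'   in fitting (e.g. `"sn2.mono"`).
#' @return An object of class `elementaryStep`.
#' @export
elementaryStep <- function(reactants, products, params, label) {
  checkStoich <- function(v, what) {
    if (length(v) == 0L || is.null(names(v)) || any(!nzchar(names(v))))
      stop(what, " must be a named vector")
    if (any(v != round(v)) || any(v < 1))
      stop(what, " coefficients must be positive integers")
    stats::setNames(as.integer(v), names(v))
  }
  reactants <- checkStoich(reactants, "reactants")
  products <- checkStoich(products, "products")
  molecularity <- sum(reactants)
  if (!molecularity %in% c(1L, 2L))
    stop("molecularity (sum of reactant coefficients) must be 1 or 2, got ",
         molecularity)
  stopifnot(inherits(params, "arrheniusParams"),
            is.character(label), length(label) == 1L, nzchar(label))
  structure(list(reactants = reactants, products = products,
                 params = params, label = label,
                 molecularity = molecularity),
            class = "elementaryStep")
}

#' Assemble a kinetic model
#'
#' @param species data.frame with columns `name`, `role`, `observable`
#'   (rbind of [species()] rows).
#' @param steps list of [elementaryStep()] objects with unique labels.
#' @param conservation named list of linear invariants over concentrations:
#'   each element is a named numeric vector of coefficients such that
#'   `sum(coef * conc)` is constant along every trajectory. Used by the
#'   simulator's conservation checks.
#' @param name short model name.
#' @return An object of class `kineticModel`.
#' @export
kineticModel <- function(species, steps, conservation = list(),
                         name = "custom") {
  stopifnot(is.data.frame(species),
            all(c("name", "role", "observable") %in% names(species)))
  if (anyDuplicated(species$name))
    stop("species names must be unique within a model")
  if (!any(species$observable))
    stop("a model needs at least one observable species")
  if (!length(steps) || !all(vapply(steps, inherits, TRUE, "elementaryStep")))
    stop("steps must be a non-empty list of elementaryStep objects")
  labels <- vapply(steps, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("step labels must be unique")
  referenced <- unique(unlist(lapply(steps, function(s)
    c(names(s$reactants), names(s$products)))))
  missing <- setdiff(referenced, species$name)
  if (length(missing))
    stop("steps reference unknown species: ", paste(missing, collapse = ", "))
  for (inv in conservation) {
    if (!all(names(inv) %in% species$name))
      stop("conservation law references unknown species")
  }
  structure(list(species = species, steps = stats::setNames(steps, labels),
                 conservation = conservation, name = name),
            class = "kineticModel")
}

#' @export
print.kineticModel <- function(x, ...) {
  cat(sprintf("Kinetic model '%s': %d species, %d elementary steps\n",
              x$name, nrow(x$species), length(x$steps)))
  for (s in x$steps) {
    side <- function(v) paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
                              sep = "", collapse = " + ")
    cat(sprintf("  [%s] %s -> %s   k(298 K) = %.3g, Ea = %.3g kJ/mol\n",
                s$label, side(s$reactants), side(s$products),
                rateConstant(s$params, 298.15), s$params$Ea / 1000))
  }
  invisible(x)
}

benzylationSpecies <- function(withCation) {
  sp <- rbind(
    species("1", "reactant", observable = TRUE),
    species("BnBr", "reagent", observable = FALSE),
    species("2", "product", observable = TRUE),
    species("di-2", "product", observable = TRUE))
  if (withCation)
    sp <- rbind(sp, species("BnCation", "intermediate", observable = FALSE))
  sp
}

# Conservation laws of the benzylation network. The aniline moiety is
# conserved across 1 -> 2 -> di-2; each benzyl group ends up on 2 (one) or
# di-2 (two), or sits on BnBr / the benzyl cation.
benzylationConservation <- function(withCation) {
  benzyl <- c(BnBr = 1, `2` = 1, `di-2` = 2)
  if (withCation) benzyl <- c(benzyl, BnCation = 1)
  list(aniline = c(`1` = 1, `2` = 1, `di-2` = 1), benzyl = benzyl)
}

#' Synthetic reference rate parameters for the benzylation models
#'
#' Generating parameters used by the built-in models and the synthetic-data
#' fixtures. They are synthetic values (not measured constants), designed
#' at a 308.15 K (35 degC) reference state with initial aniline
#' 0.344 mol/L: the total conversion-rate coefficient there is 1e-3 per
#' second, split 2:1 between the ionization (SN1) and concerted (SN2)
#' branches, so the branches carry comparable flux in the 30-40 degC
#' window. The SN2 branch holds the distinctly larger activation energy
#' (102.5 vs 37.5 kJ/mol), which swings the pathway commitment from
#' SN1-dominated near 0 degC to SN2-dominated near 80 degC. Capture of the
#' benzyl cation is fast and near-diffusion-limited (1000 L/(mol s), low
#' Ea), with a mono/di capture ratio of 2.
#'
#' Units: 1/s (unimolecular) or L/(mol s) (bimolecular); `Ea` in J/mol.
#'
#' @return Named list of `arrheniusParams`, one per step label:
#'   `sn2.mono`, `sn2.di` (bimolecular substitutions), `ion` (unimolecular
#'   ionization), `cap.mono`, `cap.di` (fast cation capture).
#' @export
defaultBenzylationParams <- function() {
  list(
    sn2.mono = arrheniusFromRef(9.690e-4, 102.5e3, Tref = 308.15),
    sn2.di   = arrheniusFromRef(4.845e-4, 97.5e3, Tref = 308.15),
    ion      = arrheniusFromRef(6.667e-4, 37.5e3, Tref = 308.15),
    cap.mono = arrheniusFromRef(1.0e3, 10e3),
    cap.di   = arrheniusFromRef(5.0e2, 10e3))
}

sn2Steps <- function(p) list(
  elementaryStep(c(`1` = 1, BnBr = 1), c(`2` = 1), p$sn2.mono, "sn2.mono"),
  elementaryStep(c(`2` = 1, BnBr = 1), c(`di-2` = 1), p$sn2.di, "sn2.di"))

sn1Steps <- function(p) list(
  elementaryStep(c(BnBr = 1), c(BnCation = 1), p$ion, "ion"),
  elementaryStep(c(BnCation = 1, `1` = 1), c(`2` = 1), p$cap.mono,
                 "cap.mono"),
  elementaryStep(c(BnCation = 1, `2` = 1), c(`di-2` = 1), p$cap.di,
                 "cap.di"))

#' Built-in benzylation models
#'
#' Candidate mechanisms for the mono-/dibenzylation of unprotected aniline
#' (1 + BnBr -> 2 -> di-2):
#' \describe{
#'   \item{`sn2Model()`}{two bimolecular substitutions:
#'     `1 + BnBr -> 2` and `2 + BnBr -> di-2`.}
#'   \item{`sn1Model()`}{unimolecular ionization `BnBr -> BnCation` (the
#'     rate-determining step, rate constant in 1/s) followed by fast capture
#'     `BnCation + 1 -> 2` and `BnCation + 2 -> di-2`.}
#'   \item{`borderlineModel()`}{both pathways competing: the union of the two
#'     step sets, five elementary steps on a shared species list. Zeroing one
#'     branch's rate constants reduces it exactly to the other mechanism.}
#' }
#' The benzyl cation is integrated explicitly rather than eliminated by a
#' steady-state approximation; with capture much faster than ionization its
#' concentration stays near zero and the system is stiff, which the simulator
#' handles with a stiff solver.
#'
#' @param params named list of `arrheniusParams` for the step labels used by
#'   the model; defaults to [defaultBenzylationParams()].
#' @return A [kineticModel()].
#' @export
sn2Model <- function(params = defaultBenzylationParams()) {
  sp <- benzylationSpecies(withCation = FALSE)
  kineticModel(sp, sn2Steps(params),
               conservation = benzylationConservation(FALSE), name = "sn2")
}

#' @rdname sn2Model
#' @export
sn1Model <- function(params = defaultBenzylationParams()) {
  sp <- benzylationSpecies(withCation = TRUE)
  kineticModel(sp, sn1Steps(params),
               conservation = benzylationConservation(TRUE), name = "sn1")
}

#' @rdname sn2Model
#' @export
borderlineModel <- function(params = defaultBenzylationParams()) {
  sp <- benzylationSpecies(withCation = TRUE)
  kineticModel(sp, c(sn2Steps(params), sn1Steps(params)),
               conservation = benzylationConservation(TRUE),
               name = "borderline")
}

#' Look up a built-in model by name
#'
#' @param name one of `"sn2"`, `"sn1"`, `"borderline"`.
#' @param params optional rate-parameter list, see [sn2Model()].
#' @return A [kineticModel()].
#' @export
builtinModel <- function(name, params = defaultBenzylationParams()) {
  builders <- list(sn2 = sn2Model, sn1 = sn1Model,
                   borderline = borderlineModel)
  if (!name %in% names(builders))
    stop("unknown model '", name, "'; built-ins are: ",
         paste(names(builders), collapse = ", "))
  builders[[name]](params)
}

#' Get or set model rate parameters as a flat named vector
#'
#' The fitting parameterization: per step `label`, `log10k.<label>` is
#' `log10` of the rate constant at `Tref` and `Ea.<label>` the activation
#' energy in J/mol. `setModelParams` accepts any subset of these names and
#' leaves the rest untouched.
#'
#' @param model a [kineticModel()].
#' @param theta named numeric vector of `log10k.*` / `Ea.*` entries.
#' @param Tref reference temperature, kelvin.
#' @return `getModelParams`: named numeric vector; `setModelParams`: the
#'   updated model.
#' @export
getModelParams <- function(model, Tref = 298.15) {
  out <- numeric(0)
  for (s in model$steps) {
    out[paste0("log10k.", s$label)] <- log10(rateConstant(s$params, Tref))
    out[paste0("Ea.", s$label)] <- s$params$Ea
  }
  out
}

#' @rdname getModelParams
#' @export
setModelParams <- function(model, theta, Tref = 298.15) {
  if (is.null(names(theta)) || any(!nzchar(names(theta))))
    stop("theta must be a named vector")
  for (nm in names(theta)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    kind <- parts[1]
    label <- paste(parts[-1], collapse = ".")
    if (!label %in% names(model$steps))
      stop("no step labelled '", label, "' in model '", model$name, "'")
    s <- model$steps[[label]]
    kRef <- rateConstant(s$params, Tref)
    Ea <- s$params$Ea
    if (kind == "log10k") kRef <- 10^theta[[nm]]
    else if (kind == "Ea") Ea <- theta[[nm]]
    else stop("parameter names must start with 'log10k.' or 'Ea.': ", nm)
    model$steps[[label]]$params <- arrheniusFromRef(kRef, Ea, Tref)
  }
  model
}

#' Zero out a set of steps (reduce a model to one branch)
#'
#' Marks the named steps as switched off (their rate constants evaluate to
#' exactly 0 at every temperature); used to verify that the borderline model
#' collapses to the single-mechanism models when one branch is silenced.
#'
#' @param model a [kineticModel()].
#' @param labels step labels to switch off.
#' @return The model with those steps' rates effectively zero.
#' @export
zeroSteps <- function(model, labels) {
  stopifnot(all(labels %in% names(model$steps)))
  for (lab in labels)
    model$steps[[lab]]$zeroed <- TRUE
  model
}

stepRateParams <- function(step) {
  if (isTRUE(step$zeroed)) list(A = 0, Ea = step$params$Ea)
  else step$params
}

# rate constants of every step at temperature T (kelvin), honoring zeroed
# steps
stepRateConstants <- function(model, T) {
  vapply(model$steps, function(s) {
    if (isTRUE(s$zeroed)) 0 else rateConstant(s$params, T)
  }, numeric(1))
}

#' Serialize a model to a plain list / file
#'
#' Round-trips species, steps, stoichiometry and Arrhenius parameters through
#' YAML or JSON (chosen by file extension).
#'
#' @param model a [kineticModel()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `modelAsList`: a plain list; `modelFromList`: a `kineticModel`;
#'   `readModelFile`/`writeModelFile`: the model (invisibly for write).
#' @export
modelAsList <- function(model) {
  list(
    name = model$name,
    species = lapply(seq_len(nrow(model$species)), function(i)
      as.list(model$species[i, , drop = FALSE])),
    steps = lapply(unname(model$steps), function(s) list(
      label = s$label,
      reactants = as.list(s$reactants),
      products = as.list(s$products),
      A = s$params$A, Ea = s$params$Ea)),
    conservation = lapply(model$conservation, as.list))
}

#' @rdname modelAsList
#' @param x a list produced by `modelAsList` (or parsed from file).
#' @export
modelFromList <- function(x) {
  sp <- do.call(rbind, lapply(x$species, function(r)
    species(r$name, r$role, isTRUE(r$observable))))
  steps <- lapply(x$steps, function(s)
    elementaryStep(unlist(s$reactants), unlist(s$products),
                   arrheniusParams(s$A, s$Ea), s$label))
  cons <- lapply(x$conservation, function(v) {
    v <- unlist(v)
    storage.mode(v) <- "double"
    v
  })
  kineticModel(sp, steps, conservation = cons,
               name = if (is.null(x$name)) "custom" else x$name)
}

#' @rdname modelAsList
#' @export
writeModelFile <- function(model, path) {
  x <- modelAsList(model)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path, precision = 15)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported model file extension: .", ext)
  invisible(model)
}

#' @rdname modelAsList
#' @export
readModelFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("unsupported model file extension: .", ext)
  modelFromList(x)
}
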