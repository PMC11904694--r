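#' Read / write time-course tables
#'
#' The CSV dialect: comma-separated, UTF-8, dot decimal, mandatory header
#' with columns `experiment_id, time_min, temp_C, species, yield_pct,
#' source`. Yields are percent of initial limiting substrate at the user
#' boundary (fractions are used internally).
#'
#' @param path CSV file path.
#' @return `readTimeCourses`: a `timeCourse` data.frame.
#' @export
readTimeCourses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "time_min", "temp_C", "species", "yield_pct",
            "source")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("time-course file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  if (!is.numeric(d$time_min) || !is.numeric(d$yield_pct))
    stop("time_min and yield_pct must be numeric")
  if (any(d$time_min < 0)) stop("negative sample times in ", path)
  if (any(d$yield_pct < 0) || any(d$yield_pct > 200))
    stop("yield_pct out of the plausible 0-200 range in ", path)
  class(d) <- c("timeCourse", "data.frame")
  d
}

#' @rdname readTimeCourses
#' @param tc a `timeCourse` data.frame.
#' @export
writeTimeCourses <- function(tc, path) {
  need <- c("experiment_id", "time_min", "temp_C", "species", "yield_pct",
            "source")
  stopifnot(all(need %in% names(tc)))
  utils::write.csv(as.data.frame(tc)[, need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write an assumed-error table
#'
#' CSV with columns `yield_pct`, `rel_error_pct` (percent at the file
#' boundary, fractions internally).
#'
#' @param path CSV path.
#' @return `readAssumedErrors`: an [assumedErrorTable()].
#' @export
readAssumedErrors <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("yield_pct", "rel_error_pct") %in% names(d)))
  assumedErrorTable(d$yield_pct / 100, d$rel_error_pct / 100)
}

#' @rdname readAssumedErrors
#' @param table an [assumedErrorTable()].
#' @export
writeAssumedErrors <- function(table, path) {
  utils::write.csv(data.frame(yield_pct = table$yield * 100,
                              rel_error_pct = table$relError * 100),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a WFI report as CSV
#'
#' Mirrors the printed table layout: one row per experiment, one column per
#' species, plus the per-experiment average.
#'
#' @param report a [wfiReport()].
#' @param path CSV path.
#' @export
writeWFIReport <- function(report, path) {
  stopifnot(inherits(report, "wfiReport"))
  wide <- stats::reshape(
    report$perSeries[, c("experiment_id", "species", "wfi")],
    idvar = "experiment_id", timevar = "species", direction = "wide")
  names(wide) <- sub("^wfi\\.", "", names(wide))
  wide$Ave. <- report$perExperiment$ave[
    match(wide$experiment_id, report$perExperiment$experiment_id)]
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolveModel <- function(src, params = defaultBenzylationParams()) {
  if (inherits(src, "kineticModel")) return(src)
  if (file.exists(src)) return(readModelFile(src))
  builtinModel(src, params)
}

defaultFreeParams <- function(model) {
  fitted <- intersect(names(model$steps), c("sn2.mono", "sn2.di", "ion"))
  free <- c(paste0("log10k.", fitted), paste0("Ea.", fitted))
  # only the capture ratio is identifiable when capture is fast: cap.mono
  # stays fixed at its reference value, cap.di (the ratio) is fitted
  if ("cap.di" %in% names(model$steps))
    free <- c(free, "log10k.cap.di")
  free
}

#' Run the full modeling workflow from a configuration
#'
#' Orchestrates the package's standard study: load (or synthesize)
#' experiments, fit the candidate models on the training conditions,
#' produce self-reproducibility and extrapolability WFI reports, a model
#' comparison table, and the temperature-dependent SN1/SN2 pathway-rate
#' ratio for the best borderline fit. All artifacts are CSV/JSON files in
#' `outDir`.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`studyDir`}{directory with `timecourses.csv` +
#'       `conditions.yaml` (omit together with `synth` to use packaged
#'       defaults).}
#'     \item{`synth`}{`TRUE` to generate the benchmark synthetic study.}
#'     \item{`models`}{character vector of candidates (built-in names or
#'       model-file paths); default all three built-ins.}
#'     \item{`objective`}{`"wls"` or `"wfi"`.}
#'     \item{`errorTable`}{optional assumed-error CSV to calibrate the
#'       weighted band from (default: the built-in anchors).}
#'     \item{`seed`}{integer seed for synthetic noise.}
#'     \item{`outDir`}{output directory.}
#'   }
#' @return Invisibly, a list with the study, fits, comparison table and
#'   artifact paths.
#' @export
runWorkflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- config$outDir %||% "kinwfi-out"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  errorParams <- if (!is.null(config$errorTable))
    calibrateErrorModel(readAssumedErrors(config$errorTable))
  else errorModelParams()

  if (isTRUE(config$synth) || is.null(config$studyDir)) {
    study <- makeStudy(borderlineModel(), benchmarkConditions(),
                       samplingSchedule(),
                       noiseSpec(errorParams, seed = seed))
    writeStudy(study, file.path(outDir, "study"))
  } else {
    study <- readStudy(config$studyDir)
  }
  trainIds <- attr(study$conds, "training") %||%
    unique(study$data$experiment_id)
  heldIds <- attr(study$conds, "heldout") %||% character(0)
  trainData <- study$data[study$data$experiment_id %in% trainIds, ]
  heldData <- study$data[study$data$experiment_id %in% heldIds, ]

  modelNames <- unlist(config$models) %||% c("borderline", "sn1", "sn2")
  specs <- lapply(modelNames, function(nm) {
    m <- resolveModel(nm)
    fitSpec(m, trainData, study$conds, defaultFreeParams(m),
            errorParams = errorParams,
            objective = config$objective %||% "wls")
  })
  names(specs) <- modelNames

  cmp <- compareModels(specs,
                       heldOutData = if (nrow(heldData)) heldData,
                       heldOutConds = study$conds)
  fits <- attr(cmp, "fits")
  utils::write.csv(as.data.frame(cmp),
                   file.path(outDir, "model_comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  paths <- list(comparison = file.path(outDir, "model_comparison.csv"))
  for (nm in modelNames) {
    f <- fits[[nm]]
    if (inherits(f, "error")) next
    writeWFIReport(selfReproducibility(f),
                   file.path(outDir, paste0("wfi_self_", nm, ".csv")))
    if (nrow(heldData))
      writeWFIReport(extrapolabilityCheck(f, heldData, study$conds),
                     file.path(outDir, paste0("wfi_extrap_", nm, ".csv")))
    jsonlite::write_json(
      list(model = nm, par = as.list(f$par), ssr = f$ssr,
           converged = f$converged),
      file.path(outDir, paste0("fit_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  bl <- fits[["borderline"]]
  if (!is.null(bl) && inherits(bl, "kinFit")) {
    init0 <- study$conds[[trainIds[1]]]$init
    ratio <- pathwayRatioByTemperature(bl$model, init0,
                                       tempC = seq(0, 80, by = 10))
    utils::write.csv(ratio, file.path(outDir, "pathway_ratio.csv"),
                     row.names = FALSE, quote = FALSE)
    paths$ratio <- file.path(outDir, "pathway_ratio.csv")
  }
  invisible(list(study = study, comparison = cmp, fits = fits,
                 errorParams = errorParams, paths = paths,
                 outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches the `synth`, `simulate`, `fit`, `wfi`, `compare` and `ratio`
#' subcommands used by the `inst/cli/kinwfi.R` wrapper script; see that
#' script for shell usage. Exit conventions: returns 0 on success, signals
#' a condition of class `kinwfiUserError` on bad usage (mapped to exit
#' status 1 by the wrapper; internal errors map to 2).
#'
#' @param args character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status, invisibly.
#' @export
kinwfiMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  userError <- function(...) stop(structure(
    class = c("kinwfiUserError", "error", "condition"),
    list(message = paste0(...), call = NULL)))
  if (!length(args))
    userError("usage: kinwfi <synth|simulate|fit|wfi|compare|ratio> ",
              "[options]")
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flags) {
    parser <- optparse::OptionParser(option_list = flags,
                                     prog = paste("kinwfi", cmd))
    optparse::parse_args(parser, args = rest)
  }
  o <- optparse::make_option

  switch(cmd,
    synth = {
      op <- opt(list(
        o("--out", type = "character", default = "study"),
        o("--seed", type = "integer", default = 1L),
        o("--model", type = "character", default = "borderline"),
        o("--noise", type = "character", default = "truncnorm",
          help = "truncnorm, uniform or none")))
      noise <- if (op$noise == "none") NULL
      else noiseSpec(distribution = op$noise, seed = op$seed)
      makeStudy(resolveModel(op$model), benchmarkConditions(),
                samplingSchedule(), noise, dir = op$out)
      message("study written to ", op$out)
    },
    simulate = {
      op <- opt(list(
        o("--model", type = "character", default = "borderline"),
        o("--temp", type = "double", default = 30),
        o("--bnbr-eq", type = "double", default = 1.2, dest = "bnbr_eq"),
        o("--aniline0", type = "double", default = 0.344),
        o("--times", type = "character", default = "1,2,4,8,16,32,64,128",
          help = "comma-separated minutes"),
        o("--out", type = "character", default = "simulation.csv")))
      cond <- conditions(c(`1` = op$aniline0,
                           BnBr = op$bnbr_eq * op$aniline0),
                         op$temp,
                         duration = max(as.numeric(
                           strsplit(op$times, ",")[[1]])),
                         id = "sim")
      tc <- simulateTimeCourse(resolveModel(op$model), cond,
                               as.numeric(strsplit(op$times, ",")[[1]]))
      writeTimeCourses(tc, op$out)
      message("simulation written to ", op$out)
    },
    fit = ,
    compare = {
      op <- opt(list(
        o("--config", type = "character", default = NULL),
        o("--study", type = "character", default = NULL),
        o("--models", type = "character", default = "borderline,sn1,sn2"),
        o("--objective", type = "character", default = "wls"),
        o("--seed", type = "integer", default = 1L),
        o("--out", type = "character", default = "kinwfi-out")))
      config <- if (!is.null(op$config)) yaml::read_yaml(op$config)
      else list(studyDir = op$study,
                synth = is.null(op$study),
                models = strsplit(op$models, ",")[[1]],
                objective = op$objective, seed = op$seed,
                outDir = op$out)
      res <- runWorkflow(config)
      print(res$comparison)
    },
    wfi = {
      op <- opt(list(
        o("--sim", type = "character"),
        o("--obs", type = "character"),
        o("--out", type = "character", default = "wfi_report.csv")))
      if (is.null(op$sim) || is.null(op$obs))
        userError("wfi needs --sim and --obs time-course CSVs")
      rep <- wfiReport(readTimeCourses(op$sim), readTimeCourses(op$obs))
      print(rep)
      writeWFIReport(rep, op$out)
    },
    ratio = {
      # dilute default state: the commitment ratio then reflects the rate
      # constants themselves rather than reagent depletion
      op <- opt(list(
        o("--model", type = "character", default = "borderline"),
        o("--aniline0", type = "double", default = 3.44e-4),
        o("--bnbr-eq", type = "double", default = 1.1, dest = "bnbr_eq"),
        o("--at", type = "double", default = 10),
        o("--out", type = "character", default = "pathway_ratio.csv")))
      tab <- pathwayRatioByTemperature(
        resolveModel(op$model),
        c(`1` = op$aniline0, BnBr = op$bnbr_eq * op$aniline0),
        tempC = seq(0, 80, by = 10), atTime = op$at)
      utils::write.csv(tab, op$out, row.names = FALSE, quote = FALSE)
      print(tab)
    },
    userError("unknown subcommand '", cmd, "'; built-ins are: synth, ",
              "simulate, fit, wfi, compare, ratio"))
  invisible(0L)
}
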