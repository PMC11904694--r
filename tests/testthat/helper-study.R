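# Shared synthetic-study fixtures and fitted models. The heavy multi-model
# fits are computed once per test run and reused by the fitting and
# acceptance tests.

.kinwfiCache <- new.env(parent = emptyenv())

cached <- function(name, thunk) {
  if (is.null(.kinwfiCache[[name]]))
    assign(name, force(thunk), envir = .kinwfiCache)
  .kinwfiCache[[name]]
}

benchFree <- list(
  sn2 = c("log10k.sn2.mono", "Ea.sn2.mono", "log10k.sn2.di", "Ea.sn2.di"),
  sn1 = c("log10k.ion", "Ea.ion", "log10k.cap.di"),
  borderline = c("log10k.sn2.mono", "Ea.sn2.mono", "log10k.sn2.di",
                 "Ea.sn2.di", "log10k.ion", "Ea.ion", "log10k.cap.di"))

benchStudy <- function(noise) {
  makeStudy(borderlineModel(), benchmarkConditions(), samplingSchedule(),
            noise)
}

benchSplit <- function(study) {
  list(train = study$data[study$data$experiment_id %in%
                            attr(study$conds, "training"), ],
       held = study$data[study$data$experiment_id %in%
                           attr(study$conds, "heldout"), ])
}

benchSpecs <- function(study) {
  d <- benchSplit(study)
  list(
    sn2 = fitSpec(sn2Model(), d$train, study$conds, benchFree$sn2),
    sn1 = fitSpec(sn1Model(), d$train, study$conds, benchFree$sn1),
    borderline = fitSpec(borderlineModel(), d$train, study$conds,
                         benchFree$borderline))
}

cleanStudy <- function() cached("cleanStudy", benchStudy(noise = NULL))

cleanComparison <- function() cached("cleanCmp", {
  study <- cleanStudy()
  d <- benchSplit(study)
  suppressWarnings(compareModels(benchSpecs(study), d$held, study$conds))
})

noisyStudy <- function() cached("noisyStudy",
                                benchStudy(noiseSpec(seed = 1)))

noisyComparison <- function() cached("noisyCmp", {
  study <- noisyStudy()
  d <- benchSplit(study)
  suppressWarnings(compareModels(benchSpecs(study), d$held, study$conds))
})

comparisonRow <- function(cmp, model) cmp[cmp$model == model, ]
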