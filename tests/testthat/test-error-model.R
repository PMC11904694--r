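test_that("the Stirling curve starts at a and decays to the a - b/k plateau", {
  for (abk in list(c(1, -9, -10), c(0.8, -5, -8), c(1.2, -9, -10))) {
    a <- abk[1]; bk <- abk[2:3]
    p <- errorModelParams(a = a, b = bk[1], k = bk[2])
    expect_equal(stirlingError(0, p), a, tolerance = 1e-14)
    expect_equal(stirlingError(50, p), a - bk[1] / bk[2], tolerance = 1e-9)
    x <- seq(0, 1, by = 0.05)
    expect_true(all(diff(stirlingError(x, p)) < 0))  # strictly decreasing
  }
  # canonical parameters: 100% at zero conversion, 10% plateau,
  # ~14.5% at 30% yield
  p0 <- errorModelParams(a = 1, b = -9, k = -10)
  expect_equal(stirlingError(0, p0), 1.0)
  expect_equal(p0$a - p0$b / p0$k, 0.1, tolerance = 1e-14)
  expect_equal(stirlingError(0.3, p0), 1 + 0.9 * expm1(-3),
               tolerance = 1e-14)
  expect_equal(stirlingError(0.3, p0), 0.1448084, tolerance = 1e-6)
})

test_that("the k -> 0 limit of the curve is the linear form a + b*x", {
  x <- seq(0, 1, by = 0.1)
  expect_equal(kinwfi:::stirlingCurve(x, 1, -0.5, 0), 1 - 0.5 * x,
               tolerance = 1e-12)
  expect_equal(kinwfi:::stirlingCurve(x, 1, -0.5, -1e-9),
               1 - 0.5 * x, tolerance = 1e-6)
})

test_that("parameter constraints on the error curve are enforced", {
  expect_error(errorModelParams(a = 1, b = 2, k = -1), "negative")
  expect_error(errorModelParams(a = 1, b = -1, k = 2), "negative")
  expect_error(errorModelParams(a = 0.5, b = -60, k = -10), "plateau")
})

test_that("calibration recovers exact curve parameters (self-consistency)", {
  x <- seq(0, 1, by = 0.1)
  tab <- assumedErrorTable(x, kinwfi:::stirlingCurve(x, 1, -9, -10))
  p <- calibrateErrorModel(tab)
  expect_equal(p$a, 1, tolerance = 1e-6)
  expect_equal(p$b, -9, tolerance = 1e-5)
  expect_equal(p$k, -10, tolerance = 1e-5)
})

test_that("calibration on the standard anchor table matches the direct oracle", {
  # frozen from an independent Nelder-Mead least-squares fit of the
  # five anchors
  p <- calibrateErrorModel(defaultAssumedErrors())
  expect_equal(p$a, 1.00285, tolerance = 1e-3)
  expect_equal(p$b, -7.5135, tolerance = 1e-2)
  expect_equal(p$k, -8.2115, tolerance = 1e-2)
  expect_lt(attr(p, "ssr"), 5.0e-4 * 1.01)
  # the fitted continuous curve stays close to every anchor
  fx <- stirlingError(defaultAssumedErrors()$yield, p)
  expect_lt(max(abs(fx - defaultAssumedErrors()$relError)), 0.02)
})

test_that("underdetermined calibration tables are rejected", {
  expect_error(calibrateErrorModel(data.frame(yield = c(0, 1),
                                              relError = c(1, 0.1))),
               "at least 3")
  expect_error(assumedErrorTable(c(0.3, 0.1), c(0.2, 0.5)), "increasing")
  expect_error(assumedErrorTable(c(0, 0.5), c(1, 1.7)), "relative errors")
})

test_that("the weighted band brackets the simulated yield, clipped at zero", {
  # relative-error reading of the standard anchors: 50% error at 10% yield
  # spans 5-15%, 10% at 50% spans 45-55%
  pHalf <- errorModelParams(a = 0.5, b = -1e-6, k = -1e-3)  # ~flat 50%
  b1 <- errorBand(0.10, pHalf)
  expect_equal(c(b1$lower, b1$upper), c(0.05, 0.15), tolerance = 1e-3)
  expect_equal(bandHalfWidth(0.10, pHalf), 0.5 * 0.10, tolerance = 1e-3)

  p0 <- errorModelParams()   # canonical curve, ~10% plateau
  b2 <- errorBand(0.50, p0)
  expect_equal(b2$lower, 0.45, tolerance = 0.01)
  expect_equal(b2$upper, 0.55, tolerance = 0.01)

  b0 <- errorBand(0, p0)
  expect_equal(c(b0$lower, b0$upper), c(0, p0$floor))
  # low simulated yields keep a nonzero band via the floor
  expect_true(all(bandHalfWidth(c(0, 1e-4, 0.001), p0) == p0$floor))
})

test_that("absolute error is the symmetric |Ys - Ye|", {
  expect_identical(absoluteError(0.4, 0.4), 0)
  expect_equal(absoluteError(0.4, 0.5), 0.1, tolerance = 1e-15)
  set.seed(7)
  x <- runif(20); y <- runif(20)
  expect_identical(absoluteError(x, y), absoluteError(y, x))
})

# build matched sim/obs series with prescribed band-relative displacements
seriesPair <- function(dispFrac, params = errorModelParams(),
                       ys = c(0.05, 0.15, 0.35, 0.60, 0.80, 0.95)) {
  n <- length(ys)
  times <- 2^(seq_len(n))
  w <- bandHalfWidth(ys, params)
  sim <- data.frame(experiment_id = "e", time_min = times, temp_C = 25,
                    species = "2", yield_pct = ys * 100,
                    source = "simulated")
  obs <- sim
  obs$yield_pct <- (ys + dispFrac * w) * 100
  obs$source <- "experimental"
  list(sim = sim, obs = obs)
}

test_that("WFI is 0 on the curve, 1 on the band edge, and averages ratios", {
  sp <- seriesPair(0)
  expect_identical(wfi(sp$sim, sp$obs), 0)

  spEdge <- seriesPair(1)
  expect_equal(wfi(spEdge$sim, spEdge$obs), 1, tolerance = 1e-12)
  spEdge2 <- seriesPair(-1)
  expect_equal(wfi(spEdge2$sim, spEdge2$obs), 1, tolerance = 1e-12)

  # alternating displacements of 0.5 w and 1.5 w average to exactly 1
  spAlt <- seriesPair(rep(c(0.5, 1.5), 3))
  expect_equal(wfi(spAlt$sim, spAlt$obs), 1, tolerance = 1e-12)

  spIn <- seriesPair(runif(6, -0.9, 0.9))
  expect_lt(wfi(spIn$sim, spIn$obs), 1)
})

test_that("WFI is invariant to the percent vs fraction reporting scale", {
  set.seed(11)
  sp <- seriesPair(runif(6, -1, 1))
  v1 <- wfi(sp$sim, sp$obs)
  # same series handed over as fractions with the floor rescaled must give
  # the same index when re-expressed in percent
  params <- errorModelParams()
  m <- kinwfi:::matchSeries(sp$sim, sp$obs)
  v2 <- mean(abs(m$Ys - m$Ye) /
               pmax(stirlingError(m$Ys, params) * m$Ys, params$floor))
  expect_equal(v1, v2, tolerance = 1e-14)
})

test_that("growing any single deviation never decreases the WFI", {
  set.seed(3)
  disp <- runif(6, -0.8, 0.8)
  base <- wfi(seriesPair(disp)$sim, seriesPair(disp)$obs)
  for (i in seq_along(disp)) {
    d2 <- disp
    d2[i] <- d2[i] + sign(d2[i]) * 0.4
    sp <- seriesPair(d2)
    expect_gte(wfi(sp$sim, sp$obs), base)
  }
})

test_that("equal relative deviations cost less at low yield than high yield", {
  params <- errorModelParams()
  # being 20% off in relative terms is tolerable early (the relative band
  # is ~43% wide at 10% yield) but breaks the ~10% band at 80% yield
  penalty <- function(ys, relDev) relDev * ys / bandHalfWidth(ys, params)
  expect_lt(penalty(0.10, 0.2), 0.5)
  expect_gt(penalty(0.80, 0.2), 1.5)
  ys <- seq(0.02, 1, by = 0.02)
  expect_true(all(diff(penalty(ys, 0.2)) > 0))
})

test_that("WFI rejects mismatched or empty series and drops t = 0 by default", {
  sp <- seriesPair(0.2)
  obsShift <- sp$obs
  obsShift$time_min <- obsShift$time_min + 0.5
  expect_error(wfi(sp$sim, obsShift), "no simulated counterpart")
  expect_error(wfi(sp$sim, sp$obs[0, ]), "empty")

  obs0 <- sp$obs
  obs0$time_min[1] <- 0
  sim0 <- sp$sim
  sim0$time_min[1] <- 0
  v <- wfi(sim0, obs0)
  m <- kinwfi:::matchSeries(sim0[-1, ], obs0[-1, ])
  expect_equal(v, mean(abs(m$Ys - m$Ye) /
                         bandHalfWidth(m$Ys, errorModelParams())),
               tolerance = 1e-14)
})

test_that("the WFI report mirrors the per-species table layout", {
  sp1 <- seriesPair(0)
  sp2 <- seriesPair(0.5)
  sp2$sim$species <- sp2$obs$species <- "di-2"
  sim <- rbind(sp1$sim, sp2$sim)
  obs <- rbind(sp1$obs, sp2$obs)
  rep <- wfiReport(sim, obs)
  expect_identical(nrow(rep$perSeries), 2L)
  expect_equal(rep$perSeries$wfi[rep$perSeries$species == "2"], 0)
  expect_equal(rep$perExperiment$ave,
               mean(rep$perSeries$wfi), tolerance = 1e-14)
  expect_equal(pooledWFI(rep), rep$perExperiment$ave)

  # identical sim/obs give an all-zero report
  repZero <- wfiReport(sim, sim)
  expect_true(all(repZero$perSeries$wfi == 0))

  # species missing from the simulation are flagged and excluded
  obsExtra <- rbind(obs, transform(sp1$obs, species = "ghost"))
  expect_warning(repNA <- wfiReport(sim, obsExtra), "ghost")
  expect_true(is.na(repNA$perSeries$wfi[repNA$perSeries$species ==
                                          "ghost"]))
  expect_equal(repNA$perExperiment$ave, rep$perExperiment$ave,
               tolerance = 1e-14)
})
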