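# minimal two-species models used by the closed-form oracles
secondOrderModel <- function(k) {
  sp <- rbind(species("A", "reactant", TRUE),
              species("B", "reagent", FALSE),
              species("C", "product", TRUE))
  kineticModel(sp, list(elementaryStep(c(A = 1, B = 1), c(C = 1),
                                       arrheniusParams(k, 0), "s")),
               name = "secondorder")
}

test_that("mass-action right-hand sides match their textbook forms", {
  sp <- rbind(species("A", "reactant", TRUE), species("B", "product", TRUE))
  m <- kineticModel(sp, list(elementaryStep(c(A = 1), c(B = 1),
                                            arrheniusParams(0.3, 0), "u")))
  rhs <- buildRateEquations(m)
  d <- rhs(c(A = 2, B = 0), T = 300)
  expect_equal(d[["A"]], -0.3 * 2, tolerance = 1e-14)
  expect_equal(d[["B"]], 0.3 * 2, tolerance = 1e-14)

  mb <- sn2Model()
  rhsb <- buildRateEquations(mb)
  st <- c(`1` = 0.2, BnBr = 0.5, `2` = 0.1, `di-2` = 0.05)
  k <- rateConstant(mb$steps[["sn2.mono"]]$params, 313.15)
  d <- rhsb(st, T = 313.15)
  kdi <- rateConstant(mb$steps[["sn2.di"]]$params, 313.15)
  expect_equal(d[["1"]], -k * 0.2 * 0.5, tolerance = 1e-12)
  expect_equal(d[["2"]], k * 0.2 * 0.5 - kdi * 0.1 * 0.5, tolerance = 1e-12)
})

test_that("the borderline RHS equals a naive per-step flux summation", {
  m <- borderlineModel()
  rhs <- buildRateEquations(m)
  set.seed(42)
  for (i in 1:5) {
    st <- stats::setNames(runif(5, 0, 0.6), m$species$name)
    T <- runif(1, 273, 353)
    # brute-force oracle: loop over steps, accumulate signed fluxes
    d0 <- stats::setNames(numeric(5), m$species$name)
    for (s in m$steps) {
      rate <- rateConstant(s$params, T)
      for (r in names(s$reactants)) rate <- rate * st[[r]]^s$reactants[[r]]
      for (r in names(s$reactants))
        d0[r] <- d0[r] - s$reactants[[r]] * rate
      for (p in names(s$products))
        d0[p] <- d0[p] + s$products[[p]] * rate
    }
    expect_equal(rhs(st, T), d0, tolerance = 1e-12)
  }
})

test_that("zero rates leave all concentrations at their initial values", {
  m <- zeroSteps(borderlineModel(), names(borderlineModel()$steps))
  tc <- simulateTimeCourse(m, benchmarkConditions()$exp1, c(1, 10, 100))
  expect_equal(tc$yield_pct[tc$species == "1"], rep(100, 3),
               tolerance = 1e-10)
  expect_equal(tc$yield_pct[tc$species == "2"], rep(0, 3),
               tolerance = 1e-10)
})

test_that("an equal-concentration second-order step matches 1/[A] = 1/[A]0 + kt", {
  k <- 2e-3; A0 <- 0.4
  cond <- conditions(c(A = A0, B = A0), 25, duration = 200, id = "2nd")
  times <- c(0.5, 1, 2, 5, 10, 30, 60, 120, 200)
  tc <- simulateTimeCourse(secondOrderModel(k), cond, times)
  a <- tc$yield_pct[tc$species == "A"] / 100 * A0
  exact <- 1 / (1 / A0 + k * times * 60)
  expect_lt(max(abs(a - exact) / exact), 1e-6)
})

test_that("a large excess of reagent approaches the pseudo-first-order limit", {
  k <- 1e-3; A0 <- 1e-3; B0 <- 1.0   # 1000 equivalents
  cond <- conditions(c(A = A0, B = B0), 25, duration = 60, id = "pfo")
  times <- c(1, 2, 5, 10, 20, 40, 60)
  tc <- simulateTimeCourse(secondOrderModel(k), cond, times)
  yC <- tc$yield_pct[tc$species == "C"] / 100
  # exact unequal-concentration closed form
  kt <- k * times * 60
  Aexact <- A0 * (B0 - A0) / (B0 * exp((B0 - A0) * kt) - A0)
  expect_lt(max(abs((1 - yC) * A0 - Aexact) / Aexact), 1e-6)
  # pseudo-first-order approximation: relative error O([A]0/[B]0)
  pfo <- 1 - exp(-k * B0 * times * 60)
  expect_lt(max(abs(yC - pfo) / pmax(pfo, 1e-3)), 2e-3)
})

test_that("conservation laws hold to integrator tolerance on every built-in model", {
  for (builder in list(sn2Model, sn1Model, borderlineModel)) {
    m <- builder()
    for (cd in benchmarkConditions()[c("exp1", "exp4", "exp6")]) {
      # at the default solver setting drift tracks the 1e-8 relative
      # tolerance; a tighter solve pushes it to the 1e-8 target and beyond
      tc <- simulateTimeCourse(m, cd, c(1, 4, 16, 64, 256, 512))
      expect_lt(max(conservationDrift(m, attr(tc, "state"))), 1e-7)
      tcT <- simulateTimeCourse(m, cd, c(1, 4, 16, 64, 256, 512),
                                rtol = 1e-10, atol = 1e-12)
      expect_lt(max(conservationDrift(m, attr(tcT, "state"))), 1e-8)
    }
  }
})

test_that("reported yields are insensitive to a 10x tighter solver tolerance", {
  m <- borderlineModel()
  cd <- benchmarkConditions()$exp2
  t1 <- simulateTimeCourse(m, cd, c(1, 8, 64, 512))
  t2 <- simulateTimeCourse(m, cd, c(1, 8, 64, 512),
                           rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(t1$yield_pct - t2$yield_pct)) / 100, 1e-6)
})

test_that("a constant profile equals a piecewise profile with equal endpoints", {
  m <- borderlineModel()
  init <- c(`1` = 0.344, BnBr = 0.413)
  cdA <- conditions(init, 35, duration = 128, id = "iso")
  cdB <- conditions(init,
                    data.frame(time_min = c(0, 50, 128),
                               temp_C = c(35, 35, 35)),
                    duration = 128, id = "pw")
  tA <- simulateTimeCourse(m, cdA, c(1, 4, 16, 64, 128))
  tB <- simulateTimeCourse(m, cdB, c(1, 4, 16, 64, 128))
  expect_lt(max(abs(tA$yield_pct - tB$yield_pct)) / 100, 1e-7)
})

test_that("a genuine temperature ramp speeds the reaction up mid-run", {
  m <- borderlineModel()
  init <- c(`1` = 0.344, BnBr = 0.413)
  ramp <- conditions(init,
                     data.frame(time_min = c(0, 64, 128),
                                temp_C = c(20, 50, 50)),
                     duration = 128, id = "ramp")
  iso <- conditions(init, 20, duration = 128, id = "iso20")
  tR <- simulateTimeCourse(m, ramp, c(64, 128))
  tI <- simulateTimeCourse(m, iso, c(64, 128))
  conv <- function(tc, t) 100 - tc$yield_pct[tc$species == "1" &
                                               tc$time_min == t]
  expect_gt(conv(tR, 128), conv(tI, 128))
  # compiled and R backends agree on the ramp
  tRr <- simulateTimeCourse(m, ramp, c(64, 128), backend = "R")
  expect_lt(max(abs(tR$yield_pct - tRr$yield_pct)) / 100, 1e-6)
})

test_that("simulated yields are reported at exactly the requested times", {
  tc <- simulateTimeCourse(sn2Model(), benchmarkConditions()$exp1,
                           c(3, 7, 11))
  expect_identical(sort(unique(tc$time_min)), c(3, 7, 11))
  expect_true(all(tc$yield_pct >= 0))
  expect_error(simulateTimeCourse(sn2Model(), benchmarkConditions()$exp1,
                                  c(1, 9999)), "within")
})

test_that("pathway rates and their ratio behave at the edge cases", {
  m <- borderlineModel()
  st <- list(`1` = 0.3, BnBr = 0.4, `2` = 0.05, `di-2` = 0, BnCation = 0)

  mNoIon <- zeroSteps(m, "ion")
  expect_equal(pathwayRates(mNoIon, st, 313.15)$ratio, 0)

  # symmetry construction: choose T and state so both fluxes are equal
  pr <- pathwayRates(m, st, 313.15)
  stEq <- st
  stEq$`1` <- st$`1` * pr$sn1 / pr$sn2   # rescale aniline to equalize
  prEq <- pathwayRates(m, stEq, 313.15)
  expect_equal(prEq$ratio, 1, tolerance = 1e-12)

  both0 <- zeroSteps(m, c("ion", "sn2.mono"))
  pr0 <- pathwayRates(both0, st, 313.15)
  expect_false(pr0$defined)
  expect_true(is.na(pr0$ratio))
  expect_error(pathwayRates(sn2Model(), st, 313.15), "branches")
})

test_that("the SN1/SN2 commitment ratio falls monotonically with temperature", {
  # the SN2 branch carries the larger Ea, so heating shifts flux toward it
  m <- borderlineModel()
  # dilute reference state (0.344 mmol/L): conversion at 10 min is
  # negligible, so the ratio tracks the rate constants cleanly
  tab <- pathwayRatioByTemperature(m, c(`1` = 3.44e-4, BnBr = 1.1 * 3.44e-4),
                                   tempC = seq(0, 79, by = 10))
  expect_true(all(diff(tab$ratio) < 0))
  expect_true(all(tab$rate_sn1 > 0) && all(tab$rate_sn2 > 0))
})
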