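---
title: "Mechanism-oriented kinetic modeling with a weighted fitting index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-oriented kinetic modeling with a weighted fitting index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinwfi)
```

## The problem

Kinetic models of multistep reactions are sets of simultaneous mass-action
rate equations built from elementary steps. Nonlinear least squares finds
the best parameters *given* a set of steps, but classical statistical
indicators (weighted sums of squares, confidence intervals) cannot tell
whether the set of steps itself is right: a structurally wrong model can
interpolate its own training data beautifully and still fail outside the
trained range. Because the rate law is a physical model, the decisive test
of a mechanism is **extrapolability** — predicting experiments at conditions
outside the training window with no refitting.

`kinwfi` implements this workflow for a concrete, classically ambiguous
chemistry: the competing mono- and dibenzylation of unprotected aniline
(`1 + BnBr -> 2 -> di-2`), where nucleophilic substitution at the benzylic
center can proceed through a concerted bimolecular attack (SN2), through
unimolecular ionization to a benzyl cation followed by fast capture (SN1),
or through both at once — the *borderline* mechanism, five elementary
steps:

| step | rate law | units of k |
|---|---|---|
| `sn2.mono` | `1 + BnBr -> 2` | L/(mol s) |
| `sn2.di`   | `2 + BnBr -> di-2` | L/(mol s) |
| `ion`      | `BnBr -> BnCation` (rds of the SN1 branch) | 1/s |
| `cap.mono` | `BnCation + 1 -> 2` | L/(mol s) |
| `cap.di`   | `BnCation + 2 -> di-2` | L/(mol s) |

All steps have integer orders: elementary mechanisms imply integer orders
in every species, and fractional-order fits, however good at
interpolation, extrapolate poorly. The base (DIPEA, 1.5 eq throughout) and
the bromide leaving group never enter the rate laws: the candidate
mechanisms show no base-order dependence and the base is in constant
excess; this is a documented model assumption, not an omission. Ionization
is treated as irreversible (no common-ion return). The benzyl cation is
integrated explicitly rather than eliminated by a quasi-steady-state
approximation — five explicit ODEs are what the five-step model means —
which makes the system stiff when capture is fast; the simulator therefore
uses a stiff solver throughout.

## The weighted error band and the WFI

Experimental conversion yields (percent of initial aniline, measured by
HPLC against an internal standard) are heteroscedastic in a structured
way: relative scatter is large at low yields and early times, small near
full conversion. A practical continuous description is the exponential-
decay ("Stirling growth") curve

$$ f(x) = a + \frac{b}{k}\left(e^{kx} - 1\right), \qquad b, k < 0, $$

which starts at `a` at zero conversion and decays to a plateau of
`a - b/k`. The package defaults `a = 1, b = -9, k = -10` encode 100%
relative error at zero conversion and a 10% plateau; they reproduce the
standard anchor table (50% assumed error at 10% yield, 10% at 50% yield
and above) and can be recalibrated from any assumed-error table with
`calibrateErrorModel()` (bounded multi-start least squares; bounds
`a <= 1.5`, `b, k ∈ [-100, 0)`).

The error band is centered on the **simulated** curve, not on the data:
model uncertainty is the quantity being minimized, and simulated curves
are continuous, so a band around them gives every experimental point a
well-defined distance. The half-width at simulated yield fraction
$Y_s$ is $w = \max(f(Y_s)\,Y_s,\ \text{floor})$; the floor (default 0.005,
half a percentage point) represents the analytical limit of quantification
and keeps the band non-degenerate where the simulation predicts zero.
Note that $w$ grows with yield in absolute terms even though the relative
width $f$ shrinks: the band is *relatively* forgiving early and strict
late, which is the intended weighting.

The **weighted fitting index** of a matched series of $n$ points is

$$ \mathrm{WFI} = \frac{1}{n}\sum_{i=1}^{n}
   \frac{|Y_{s,i} - Y_{e,i}|}{\max(f(Y_{s,i})\,Y_{s,i},\ \text{floor})}. $$

WFI is 0 when the data sit on the curve, exactly 1 when every point sits
on the band edge, and below 1 whenever the average distance is within the
weighted range — the index's defining contract. The per-point denominator
makes it directly comparable across species, experiments and models.
The $t = 0$ point is excluded by default: both series vanish there by
construction and the band degenerates to the floor, so it carries no
model information.

## Sampling design

Simulated curve *shapes* (exponential, sigmoidal, higher-order) are
distinguished by early points, where the rate of change is largest;
late-stage points add little shape information but accumulate bias.
`samplingSchedule()` therefore defaults to exponential, sparse sampling
(1, 2, 4, ..., 512 min, ten points), and `demoCurves()` constructs the
classic two-curves demonstration: an exponential and a sigmoidal time
course that agree at uniform late sample times and are separated only by
an added early point.

## Parameter estimation

`fitKinetics()` minimizes band-weighted residuals $(Y_s - Y_e)/w$ jointly
over all training experiments with bounded Levenberg–Marquardt
(`minpack.lm`). Design choices that matter:

* **Parameterization.** Each free step contributes `log10 k(298.15 K)` and
  `Ea` (J/mol) rather than `(A, Ea)`, which are almost perfectly
  correlated on a 30 °C data window; `A` is recovered algebraically.
* **Identifiability.** When capture is fast, only the ionization constant
  and the capture ratio `k(cap.di)/k(cap.mono)` are practically
  identifiable; the default free set fixes `cap.mono` at a large reference
  value (1000 L/(mol s), Ea 10 kJ/mol, a near-diffusion-limited capture)
  and fits `cap.di`. Freeing any `Ea` requires training data at two or
  more temperatures, enforced with an explicit error.
* **Multi-start strategy.** Starts are deterministic: a ladder of six
  chemically anchored points (every slow-step `log10 k` at a common level
  from −6 to −1, intermediate-consuming steps started fast, all `Ea` at a
  typical 70 kJ/mol), plus low-discrepancy Halton filler spanning the
  bounds. All starts are screened by objective value and the best few
  fully optimized. `compareModels()` additionally fits candidates in order
  of increasing complexity and *seeds* each composite model from the
  single-mechanism solutions (directly and with the seeded slow constants
  halved, since previously exclusive pathways now share flux). This
  cascade is what a practitioner does by hand when assembling a
  competing-pathway model; it is how the noise-free benchmark recovery in
  the test suite reaches the exact zero-residual optimum.
* **Derivative step size.** The residuals pass through an adaptive ODE
  solver with relative tolerance 1e-8, so forward differences at the
  machine-epsilon step are dominated by integration noise;
  `epsfcn = 1e-8` keeps the finite-difference Jacobian step above that
  floor.
* **Objectives.** `"wls"` squares the band-relative residuals; `"wfi"`
  minimizes their absolute sum (proportional to the WFI itself) through a
  square-root transform in the same least-squares engine. On well-
  specified noise-free data both share the zero-residual optimum.
* **Uncertainty.** Local curvature-based standard errors are reported but
  deliberately de-emphasized: such statistics cannot detect a wrong model,
  which is the failure mode this package is about. Model adequacy is
  judged by the WFI tables and, above all, by extrapolation.

`selfReproducibility()` scores the fit on its own training experiments;
`extrapolabilityCheck()` scores untouched held-out conditions and refuses
to run if the fitted parameters were modified (a fingerprint guards the
no-refit guarantee).

## The synthetic study

Real HPLC time courses live outside the package, so `makeStudy()`
generates studies with the statistical structure the methodology assumes.
The benchmark design mirrors the standard four-experiment training set —
isothermal batches in MeCN at 40 °C/BnBr 1.2 eq, 30 °C/1.3 eq,
50 °C/1.1 eq, 20 °C/1.4 eq, aniline 0.344 mol/L, DIPEA 1.5 eq — plus two
extrapolation conditions outside that range, 0 °C/2.1 eq and
79 °C/1.05 eq, all sampled on the exponential schedule.

Noise is tied to the same weighted band the evaluation uses: at each
point a deviation is drawn from a truncated normal with `sd = w/2`,
truncated at the band edges (so the band spans ±2 sd), or uniformly
within the band. This reproduces the large-relative-scatter-at-low-yield
structure of real quantitation; optional systematic bias and
sampling-time jitter emulate the non-random error components and default
to zero. What the generator does **not** emulate: drifting instrument
response, correlated errors within a chromatogram, quenching artifacts,
or model error (the truth really is one of the candidate mechanisms).
Passing tests on this generator therefore demonstrate the machinery —
conservation, recovery, discrimination, calibration — not the field
performance of any specific laboratory assay.

The generating rate parameters (`defaultBenzylationParams()`) are
synthetic reference values, not measured constants. They were chosen, as
part of the fixture design, so that (i) both branches carry comparable
flux in the 30–40 °C window (the ionization branch somewhat ahead, ~70/30
at 35 °C), (ii) the SN2 branch carries the distinctly larger activation
energy, making the pathway commitment swing from SN1-dominated at 0–20 °C
to SN2-dominated at 50–79 °C, and (iii) overall timescales put the
interesting dynamics inside the 1–512 min sampling window at every
design temperature. These are the conditions under which the borderline
mechanism is genuinely borderline and mechanism discrimination is
non-trivial.

## Numerical choices

* Stiff solver (`deSolve::ode`, lsoda) with `rtol = 1e-8`,
  `atol = 1e-10` mol/L; the compiled mass-action right-hand side is the
  default backend, with an R closure (`buildRateEquations()`) kept as the
  readable cross-checked reference.
* Conservation (aniline moiety and benzyl group balances) is checked
  against the integrator tolerance; tests require drift below 1e-8.
* Concentrations are clamped at zero inside rate evaluations; an
  integration that goes materially negative (beyond solver overshoot)
  aborts with a diagnostic rather than returning NaNs.
* Time is minutes at every user boundary and seconds internally; yields
  are percent externally and fractions internally.
* The SN1/SN2 commitment ratio (`pathwayRatioByTemperature()`) is
  evaluated 10 min into a simulated batch; its shell default uses a dilute
  reference state (0.344 mmol/L) where 10-min conversion is negligible, so
  the ratio reflects the rate constants rather than reagent depletion.

## Problem sizes

The test-suite and acceptance studies use the benchmark design as is:
4 training + 2 extrapolation experiments, 10 sample times, 3 observable
species (120 training points), with the three candidate models fitted by
the cascade described above. These sizes keep a full
generate–fit–discriminate round comfortably within an interactive
session on a single core while leaving every qualitative conclusion
intact.

## Known limitations

* Only integer-order, irreversible uni/bimolecular steps: no reversible
  equilibria, catalytic cycles, dosing profiles or heat-balance effects.
* The WFI is a descriptive index; the package intentionally offers no
  p-values or distribution theory for it.
* Heteroscedasticity is modeled through a single yield-dependent curve
  per study; per-species error curves are not supported.
* Extrapolation scoring needs the held-out conditions' initial
  concentrations and temperature profiles to be trusted as given.
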