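# myelinpet

Kinetic quantification of dynamic brain PET with a myelin-binding tracer
and arterial blood sampling, aimed at studies that grade multiple
sclerosis (MS) lesions by myelin density.

Myelin tracers are cleared from plasma quickly (only ~19% intact tracer at
10 min) and bind white matter irreversibly over a 60-min scan, so a static
uptake image is not quantitative. The package implements the full
quantification chain:

* **Input function** — cross-calibration of the continuous arterial
  detector curve against manual samples, a Hill model of the intact parent
  fraction `PF(t) = 1 − a·t^b/(t^b + c)`, and composition of the
  metabolite-corrected plasma input `C_p = C_wb · R(t) · PF(t)`.
* **Compartment models** — 1T2K, 2T3K and 2T4K with fractional blood
  volume, fitted by bounded weighted Levenberg–Marquardt on exact
  frame-averaged model curves (closed-form convolution of the
  piecewise-linear input, C++ core). Outputs include the net influx rate
  `Ki = K1·k3/(k2 + k3)` — the myelin-density index — plus `VT`, `BPnd`,
  percent standard errors (delta method for macroparameters), and AIC/AICc.
* **Simplified estimators** — Patlak and Logan graphical analyses, the
  multiple-linear MLAIR1/MLAIR2 estimators (MLAIR2 reads Ki directly off a
  regression coefficient, which keeps it stable at voxel level), SUV over
  40–50 and 50–60 min windows, and voxel-wise parametric maps.
* **Study statistics** — %SE>25% reliability filtering, AIC
  model-preference tables, Pearson/OLS method-comparison, gated t-tests
  for grey/white matter, Mann–Whitney lesion-vs-NAWM tests, and the
  radiological lesion classifier (active / black hole / demyelinated /
  partially myelinated / remyelinated, with a 3-mm size gate).
* **Synthetic cohorts** — a generator that reproduces the acquisition
  design (26-frame schedule, blood sampling scheme, fast metabolism) and
  the class-wise kinetic anchors, so the entire pipeline is testable
  without patient data.

## Worked example

Build a synthetic arterial input, simulate a noisy white-matter TAC with
known kinetics, and quantify it three ways:

```r
library(myelinpet)
sched <- defaultSchedule()                  # 26 frames, 0-60.2 min
sys <- makeSyntheticInput(seed = 42)        # calibrate + Hill fit + compose
sys$calibration$factor
#> [1] 1.257723                             # recovers the 0.8 miscalibration
sys$hill
#> HillParams: a = 0.95, b = 1.5, c = 5.65 (plateau 0.05)

truth <- c(K1 = 0.25, k2 = 0.12, k3 = 0.099, vB = 0.02)   # Ki = 0.113
tac <- modelTissueCurve("2T3K", truth, sys$input, sched,
                        region = "wholeBrainWM")
tac <- addTacNoise(tac, alpha = noiseAlphaForCV(tac, 0.05), seed = 7)

fitCompartmentModel(tac, sys$input, "2T3K")
#> KineticFit 2T3K: wrss 19.33, AIC 0.30, R2 0.9926
#>    K1 = 0.2783 (3.3%), k2 = 0.1341 (9.6%), k3 = 0.0902 (6.0%), vB = 0 (se n/a)
#>    Ki = 0.1119 (1.3%)
mlair2Fit(tac, sys$input)
#> GraphicalFit mlair2: Ki = 0.1132 (n = 26, R2 = 0.9999)
patlakFit(tac, sys$input, tstar = 20)
#> GraphicalFit patlak: Ki = 0.1188 (n = 5, R2 = 0.9997)
```

All three estimators recover the generating `Ki = 0.113` mL·cm⁻³·min⁻¹ —
the compartment fit within ~1%, MLAIR2 with similar precision from a plain
linear regression, Patlak with more scatter because only the five frames
after its 20-min equilibration time contribute.

Cohort-level statistics work directly on generated ground truth; here the
grey/white-matter contrast in a six-subject healthy cohort:

```r
hc <- simulateHcKiCohort(6, seed = 1)
unlist(groupDifference(hc$gmKi, hc$wmKi)[c("t", "df", "p", "testUsed")])
#>                   t                  df                   p    testUsed
#> "-6.60482859234462"                "10" "6.041472122963e-05"   "student"
```

An end-to-end run — input construction, fits, preference table, method
comparison, lesion statistics — is one call:

```r
res <- runQuantification(pipelineConfig(simulate = cohortSpec(), seed = 1))
res$comparison    # Pearson r / slope / intercept per method and cohort
```

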