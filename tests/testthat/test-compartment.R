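test_that("degenerate and reduced topologies behave as expected", {
  sched <- fixtureSchedule; inp <- fixtureInput
  ## K1 = 0: the measured signal is pure blood volume
  tc <- modelTissueCurve("2T3K", c(K1 = 0, k2 = 0.1, k3 = 0.05, vB = 0.04),
                         inp, sched)
  wbOnly <- modelTissueCurve("1T2K", c(K1 = 0, k2 = 0.1, vB = 0.04),
                             inp, sched)
  expect_equal(activity(tc), activity(wbOnly), tolerance = 1e-12)
  expect_gt(max(activity(tc)), 0)
  ## 2T4K with k3 = 0 equals 1T2K
  a <- activity(modelTissueCurve("2T4K",
                                 c(K1 = 0.15, k2 = 0.1, k3 = 0, k4 = 0,
                                   vB = 0.03), inp, sched))
  b <- activity(modelTissueCurve("1T2K", c(K1 = 0.15, k2 = 0.1, vB = 0.03),
                                 inp, sched))
  expect_lt(max(abs(a - b)), 1e-10 * max(abs(b)))
  ## 2T3K equals 2T4K with k4 = 0
  a <- activity(modelTissueCurve("2T4K",
                                 c(K1 = 0.12, k2 = 0.14, k3 = 0.11, k4 = 0,
                                   vB = 0.02), inp, sched))
  b <- activity(modelTissueCurve("2T3K",
                                 c(K1 = 0.12, k2 = 0.14, k3 = 0.11, vB = 0.02),
                                 inp, sched))
  expect_lt(max(abs(a - b)), 1e-10 * max(abs(b)))
  ## repeated eigenvalues (discriminant zero) do not break the solver
  k <- 0.1  # k2 = k4, k3 = 0 makes theta1 = theta2 = k
  conf <- modelTissueCurve("2T4K", c(K1 = 0.2, k2 = k, k3 = 0, k4 = k,
                                     vB = 0), inp, sched)
  ref <- odeFrameAverages("2T4K", c(K1 = 0.2, k2 = k, k3 = 0, k4 = k, vB = 0),
                          inp, sched)
  expect_lt(max(abs(activity(conf) - ref)) / max(abs(ref)), 1e-6)
  ## invalid parameters rejected
  expect_error(modelTissueCurve("1T2K", c(K1 = 0.1, k2 = 0.1, k3 = 0.2),
                                inp, sched), "k3")
  expect_error(modelTissueCurve("2T3K", c(K1 = 0.1, k2 = 0.1, k4 = 0.2),
                                inp, sched), "k4")
})

test_that("analytic frame averages match a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(41)
  for (model in c("1T2K", "2T3K", "2T4K")) {
    for (i in 1:8) {
      p <- c(K1 = runif(1, 0.05, 0.6), k2 = runif(1, 0.05, 0.6),
             k3 = runif(1, 0.01, 0.3), k4 = runif(1, 0.005, 0.1),
             vB = runif(1, 0, 0.1))
      if (model == "1T2K") p[c("k3", "k4")] <- 0
      if (model == "2T3K") p["k4"] <- 0
      got <- activity(modelTissueCurve(model, p, fixtureInput,
                                       fixtureSchedule))
      ref <- odeFrameAverages(model, p, fixtureInput, fixtureSchedule)
      expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-6)
    }
  }
})

test_that("the forward model is linear in K1 at fixed rate constants", {
  sched <- fixtureSchedule; inp <- fixtureInput
  base <- c(k2 = 0.12, k3 = 0.08, vB = 0.04)
  wb <- activity(modelTissueCurve("2T3K", c(K1 = 0, base), inp, sched))
  a1 <- activity(modelTissueCurve("2T3K", c(K1 = 0.1, base), inp, sched))
  a3 <- activity(modelTissueCurve("2T3K", c(K1 = 0.3, base), inp, sched))
  expect_equal(a3 - wb, 3 * (a1 - wb), tolerance = 1e-12)
})

test_that("macroparameters follow their closed forms", {
  expect_equal(macroParameters("2T3K", c(K1 = 0.1, k2 = 0.1, k3 = 0.1)),
               c(Ki = 0.05))
  expect_equal(macroParameters("2T3K", c(K1 = 0.1, k2 = 0.1, k3 = 0)),
               c(Ki = 0))
  m <- macroParameters("2T4K", c(K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0.025))
  expect_equal(m[["VT"]], 6)
  expect_equal(m[["BPnd"]], 2)
  expect_equal(m[["Ki"]], 0.2 * 0.05 / 0.15)
  expect_equal(macroParameters("1T2K", c(K1 = 0.3, k2 = 0.15)), c(VT = 2))
  ## BPnd absent when k4 = 0
  expect_false("BPnd" %in%
                 names(macroParameters("2T4K", c(K1 = 0.2, k2 = 0.1,
                                                 k3 = 0.05, k4 = 0))))
  expect_error(macroParameters("1T2K", c(K1 = 0.1, k2 = 0)), "k2")
  expect_error(macroParameters("2T3K", c(K1 = 0.1, k2 = 0, k3 = 0)), "k2")
})

test_that("the information criterion follows its definition", {
  expect_equal(aicScore(26, 26, 3), 6)
  ## halving wrss lowers AIC by n*log(2)
  expect_equal(aicScore(26, 13, 3), 6 - 26 * log(2))
  expect_equal(aicScore(26, 26, 3, smallSample = TRUE), 6 + 24 / 22)
  expect_warning(v <- aicScore(10, 0, 2), "zero")
  expect_identical(v, -Inf)
  expect_error(aicScore(3, 1, 5))
})

test_that("noiseless fits recover the generating parameters", {
  sched <- fixtureSchedule; inp <- fixtureInput
  truth <- c(K1 = 0.12, k2 = 0.14, k3 = 0.11, vB = 0.02)
  tc <- modelTissueCurve("2T3K", truth, inp, sched)
  fit <- fitCompartmentModel(tc, inp, "2T3K")
  expect_true(fit@converged)
  for (nm in names(truth))
    expect_lt(relErr(coef(fit)[[nm]], truth[[nm]]), 1e-3)
  expect_lt(relErr(macroParams(fit)[["Ki"]], 0.0528), 1e-3)
  ## essentially zero percent standard errors on noiseless data
  expect_lt(percentSE(fit, "Ki"), 0.1)
  ## fixing vB at its true value: same Ki, one fewer parameter, AIC
  ## penalty term smaller by 2 at (numerically) equal wrss
  fitF <- fitCompartmentModel(tc, inp, "2T3K", vB = 0.02)
  expect_equal(macroParams(fitF)[["Ki"]], macroParams(fit)[["Ki"]],
               tolerance = 1e-6)
  expect_equal(sum(!fitF@fixed), sum(!fit@fixed) - 1)
  expect_error(percentSE(fitF, "vB"), "fixed")
  ## K1/k2-fixed reparameterization preserves the ratio exactly
  fitR <- fitCompartmentModel(tc, inp, "2T3K", k1k2Ratio = 0.12 / 0.14)
  expect_equal(coef(fitR)[["K1"]] / coef(fitR)[["k2"]], 0.12 / 0.14)
  expect_lt(relErr(macroParams(fitR)[["Ki"]], 0.0528), 1e-3)
})

test_that("overparameterized fits flag non-identifiable constants", {
  sched <- fixtureSchedule; inp <- fixtureInput
  tc <- modelTissueCurve("1T2K", c(K1 = 0.12, k2 = 0.14, vB = 0.02),
                         inp, sched)
  fit4 <- fitCompartmentModel(tc, inp, "2T4K")
  ## VT still recovered near K1/k2 while k3/k4 are poorly determined
  expect_lt(relErr(macroParams(fit4)[["VT"]], 0.12 / 0.14), 0.01)
  expect_gt(percentSE(fit4, "k4"), percentSE(fit4, "k2"))
  expect_gt(max(percentSE(fit4, "k3"), percentSE(fit4, "k4")), 50)
})
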