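test_that("the arterial curve model is delayed, continuous and peaked", {
  p <- defaultFengParams()
  expect_equal(fengInput(p, c(0, 0.25, p$tau)), c(0, 0, 0))
  ## continuity at the delay: -A2 - A3 + A2 + A3 = 0
  expect_lt(abs(fengInput(p, p$tau + 1e-9)), 1e-4)
  ## peak location: fine-grid argmax agrees with the root of the
  ## closed-form derivative within one grid step
  grid <- seq(p$tau, 5, by = 1e-4)
  peakGrid <- grid[which.max(fengInput(p, grid))]
  dC <- function(t) {
    u <- t - p$tau
    (p$A1 - p$l1 * (p$A1 * u - p$A2 - p$A3)) * exp(-p$l1 * u) -
      p$l2 * p$A2 * exp(-p$l2 * u) - p$l3 * p$A3 * exp(-p$l3 * u)
  }
  peakRoot <- uniroot(dC, c(p$tau + 1e-6, 5))$root
  expect_lt(abs(peakGrid - peakRoot), 2e-4)
  ## peaks within the first minute of arrival
  expect_lt(peakGrid, p$tau + 1)
  expect_error(fengInput(list(A1 = 1, A2 = 1, A3 = 1, l1 = 0.1, l2 = 0.5,
                              l3 = 0.01, tau = 0), 1))
})

test_that("simulated blood data honours calibration and metabolism anchors", {
  clean <- simulateBloodData(detectorNoise = 0, miscalibration = 1, seed = 1)
  onCurve <- approx(clean$continuous$time, clean$continuous$wholeBlood,
                    xout = clean$samples@time)$y
  expect_equal(onCurve, clean$samples@wholeBlood, tolerance = 1e-9)
  half <- simulateBloodData(detectorNoise = 0, miscalibration = 0.5, seed = 1)
  expect_equal(calibrateContinuousBlood(half$continuous, half$samples)$factor,
               2, tolerance = 1e-9)
  ## default metabolism: parent fraction at 10 min within one SD of the
  ## emulated cohort mean (19.4 +/- 6.9 percent)
  pf10 <- parentFraction(defaultHillParams(), 10)
  expect_gt(pf10, 0.12); expect_lt(pf10, 0.26)
})

test_that("ground-truth draws are internally consistent and anchored", {
  d <- drawKineticParams("WM", 500, seed = 9)
  expect_equal(d$Ki, d$K1 * d$k3 / (d$k2 + d$k3), tolerance = 1e-12)
  ## WM Ki anchor within Monte-Carlo error of 0.113
  expect_lt(abs(mean(d$Ki) - 0.113), 3 * 0.031 / sqrt(500) + 0.002)
  expect_true(all(d$vB >= 0.001 & d$vB <= 0.15))
  expect_identical(drawKineticParams("GM", 5, seed = 4),
                   drawKineticParams("GM", 5, seed = 4))
  d1 <- drawKineticParams("GM", 10, truthModel = "1T2K", seed = 2)
  expect_true(all(d1$k3 == 0) && all(d1$Ki == 0))
  d4 <- drawKineticParams("GM", 10, truthModel = "2T4K", seed = 2)
  expect_true(all(d4$k4 > 0))
  expect_error(drawKineticParams("cortex", 1), "unknown")
})

test_that("frame noise follows the count-statistics model", {
  tc <- fixtureTac2t3k
  expect_identical(activity(addTacNoise(tc, 0)), activity(tc))
  n1 <- addTacNoise(tc, 0.5, seed = 31)
  expect_identical(activity(n1), activity(addTacNoise(tc, 0.5, seed = 31)))
  expect_false(identical(activity(n1), activity(addTacNoise(tc, 0.5, seed = 32))))
  ## empirical per-frame sd over many replicates matches the formula
  alpha <- 0.3
  sched <- schedule(tc)
  sdTheory <- alpha * sqrt(pmax(activity(tc), 0) *
                             exp(log(2) / 20.34 * frameMidpoints(sched)) /
                             frameDuration(sched))
  reps <- vapply(1:4000, function(i)
    activity(addTacNoise(tc, alpha, seed = 50000 + i)), numeric(26))
  sdEmp <- apply(reps, 1, sd)
  live <- sdTheory > 0
  expect_lt(max(abs(sdEmp[live] - sdTheory[live]) / sdTheory[live]), 0.06)
  ## the calibration helper hits its target median CV
  a <- noiseAlphaForCV(tc, 0.05)
  act <- activity(tc)
  rel <- (a * sqrt(pmax(act, 0) * exp(log(2) / 20.34 * frameMidpoints(sched)) /
                     frameDuration(sched)) / act)[act > 0]
  expect_equal(median(rel), 0.05, tolerance = 1e-9)
})

test_that("noiseless generated TACs refit to their ground truth", {
  truth <- drawKineticParams("WM", 3, seed = 21)
  for (i in 1:3) {
    p <- unlist(truth[i, c("K1", "k2", "k3", "k4", "vB")])
    tc <- modelTissueCurve("2T3K", p, fixtureInput, fixtureSchedule)
    fit <- fitCompartmentModel(tc, fixtureInput, "2T3K")
    expect_lt(relErr(macroParams(fit)[["Ki"]], truth$Ki[i]), 1e-3)
  }
})

test_that("lesion cohorts and HC cohorts reproduce their anchors", {
  les <- simulateLesionCohort(seed = 3)
  expect_equal(nrow(les), 105 + 111 + 69 + 7)
  expect_equal(sum(les$class == "remyelinated"), 7)
  ## class means ordered by expected myelin density BH < DM < PM < RM
  mns <- tapply(les$lesionKi, les$class, mean)
  expect_true(mns[["black_hole"]] < mns[["demyelinated"]])
  expect_true(mns[["demyelinated"]] < mns[["partially_myelinated"]])
  expect_true(mns[["partially_myelinated"]] < mns[["remyelinated"]])
  hc <- simulateHcKiCohort(seed = 5)
  expect_equal(nrow(hc), 6)
  expect_true(mean(hc$wmKi) > mean(hc$gmKi))
})

test_that("generated descriptors classify back to their intended class", {
  classes <- rep(c("black_hole", "demyelinated", "partially_myelinated",
                   "remyelinated"), times = c(8, 8, 8, 4))
  d <- simulateLesionDescriptors(classes, seed = 13)
  expect_equal(as.character(classifyLesion(d)), classes)
})

test_that("whole studies are reproducible and round-trippable", {
  spec <- cohortSpec(nHC = 1, nMS = 1, regionsGM = 2, regionsWM = 2,
                     lesionCounts = c(black_hole = 2, demyelinated = 2,
                                      partially_myelinated = 2,
                                      remyelinated = 1))
  s1 <- simulateStudy(spec, seed = 77)
  s2 <- simulateStudy(spec, seed = 77)
  expect_identical(s1$subjects[[1]]$truth, s2$subjects[[1]]$truth)
  expect_identical(activity(s1$subjects[[2]]$tacs[[3]]),
                   activity(s2$subjects[[2]]$tacs[[3]]))
  expect_equal(s1$provenance$seed, 77)
  expect_equal(s1$subjects[[1]]$meta$cohort, "HC")
  expect_equal(s1$subjects[[2]]$meta$cohort, "MS")
  expect_equal(nrow(s1$subjects[[2]]$lesions), 7)
  ## write-read identity through the TAC table format
  path <- tempfile(fileext = ".csv")
  writeTacTable(s1$subjects[[1]]$tacs, path, subject = "HC01")
  back <- readTacTable(path)
  expect_equal(activity(back[[1]]), activity(s1$subjects[[1]]$tacs[[1]]))
})
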