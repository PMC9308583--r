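test_that("the cumulative integral kernel matches closed forms", {
  t10 <- seq(0, 10, by = 0.5)
  expect_equal(cumulativeIntegral(t10, rep(1, length(t10)))[length(t10)], 10)
  expect_equal(cumulativeIntegral(t10, t10)[length(t10)], 50)
  ## trapezoid error h^2/12 * int f'': ~8e-4 at 0.1-min steps, ~8e-6 at 0.01
  tf <- seq(0, 5, by = 0.1)
  ci <- cumulativeIntegral(tf, exp(-tf))
  expect_equal(ci[length(tf)], 1 - exp(-5), tolerance = 1e-3)
  tf2 <- seq(0, 5, by = 0.01)
  expect_equal(cumulativeIntegral(tf2, exp(-tf2))[length(tf2)], 1 - exp(-5),
               tolerance = 1e-5)
  ## leading triangle when the grid starts after the origin
  expect_equal(cumulativeIntegral(c(5, 10), c(1, 1)), c(2.5, 7.5))
  expect_error(cumulativeIntegral(c(1, 0.5), c(1, 1)), "sorted")
})

test_that("Patlak slope recovers Ki on irreversible data and 0 without trapping", {
  g <- patlakFit(fixtureTac2t3k, fixtureInput, tstar = 20)
  expect_equal(g@estimateName, "Ki")
  expect_lt(relErr(g@estimate, fixtureKi2t3k), 0.01)
  ## reversible truth: the apparent slope decays towards zero at late tstar
  rev <- modelTissueCurve("1T2K", c(K1 = 0.12, k2 = 0.14, vB = 0),
                          fixtureInput, fixtureSchedule)
  s25 <- patlakFit(rev, fixtureInput, 25)@estimate
  s40 <- patlakFit(rev, fixtureInput, 40)@estimate
  expect_lt(abs(s40), abs(s25))
  expect_lt(abs(s40), 0.05 * fixtureKi2t3k)
  ## frame bookkeeping on the printed schedule: one midpoint at/after 55
  ## min (the 3310-s frame), so tstar = 55 cannot support a regression,
  ## and tstar = 45 leaves exactly two frames, flagged low confidence
  expect_error(patlakFit(fixtureTac2t3k, fixtureInput, 55), "fewer than 2")
  g45 <- patlakFit(fixtureTac2t3k, fixtureInput, 45)
  expect_equal(g45@nPoints, 2)
  expect_true(g45@lowConfidence)
})

test_that("Logan slope recovers VT for reversible kinetics and flags divergence", {
  rev1 <- modelTissueCurve("1T2K", c(K1 = 0.12, k2 = 0.14, vB = 0),
                           fixtureInput, fixtureSchedule)
  g1 <- loganFit(rev1, fixtureInput, 20)
  expect_equal(g1@estimateName, "VT")
  expect_lt(relErr(g1@estimate, 0.12 / 0.14), 0.01)
  p4 <- c(K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0.05, vB = 0)
  rev2 <- modelTissueCurve("2T4K", p4, fixtureInput, fixtureSchedule)
  g2 <- loganFit(rev2, fixtureInput, 40)
  expect_lt(relErr(g2@estimate, (0.2 / 0.1) * (1 + 0.05 / 0.05)), 0.02)
  ## irreversible truth: no finite VT; the apparent slope keeps rising
  s20 <- loganFit(fixtureTac2t3k, fixtureInput, 20)@estimate
  s35 <- loganFit(fixtureTac2t3k, fixtureInput, 35)@estimate
  expect_gt(s35, s20)
})

test_that("MLAIR estimators are exact on noiseless irreversible data", {
  kiTrue <- fixtureKi2t3k
  m1 <- mlair1Fit(fixtureTac2t3k, fixtureInput)
  m2 <- mlair2Fit(fixtureTac2t3k, fixtureInput)
  expect_lt(relErr(m1@estimate, kiTrue), 0.005)
  expect_lt(relErr(m2@estimate, kiTrue), 0.005)
  ## both exact in the noise-free limit: mutual agreement within 0.1%
  expect_lt(abs(m1@estimate - m2@estimate) / kiTrue, 0.001)
  ## full 5-term variant reads the blood volume off the first coefficient
  pv <- c(K1 = 0.12, k2 = 0.14, k3 = 0.11, vB = 0.05)
  tv <- modelTissueCurve("2T3K", pv, fixtureInput, fixtureSchedule)
  m1v <- mlair1Fit(tv, fixtureInput, includeWbIntegral = TRUE)
  expect_equal(unname(m1v@coefficients["wb"]), 0.05, tolerance = 0.005)
  ## apparent Ki absorbs the (1 - vB) factor
  expect_lt(relErr(-m1v@coefficients[["iicp"]] / m1v@coefficients[["ipet"]],
                   0.95 * kiTrue), 0.005)
  ## degenerate input
  zero <- Tac(fixtureSchedule, rep(0, 26), quiet = TRUE)
  expect_error(mlair1Fit(zero, fixtureInput), "rank|degenerate")
})

test_that("MLAIR2 is more noise-robust than MLAIR1 at voxel-level noise", {
  alpha <- noiseAlphaForCV(fixtureTac2t3k, 0.20)
  est <- t(vapply(1:120, function(i) {
    tn <- addTacNoise(fixtureTac2t3k, alpha, seed = 700 + i)
    c(mlair1Fit(tn, fixtureInput)@estimate,
      mlair2Fit(tn, fixtureInput)@estimate)
  }, numeric(2)))
  expect_lt(var(est[, 2]), var(est[, 1]))
})

test_that("SUV normalizes concentration by dose per body weight", {
  sched <- parseFrameSchedule("2x600")
  tc <- Tac(sched, c(3, 3))
  expect_equal(as.numeric(suvValue(tc, c(0, 20), dose = 210, weight = 70)), 1)
  expect_equal(as.numeric(suvValue(tc, c(0, 20), dose = 420, weight = 70)), 0.5)
  ## duration weighting over unequal frames
  s2 <- parseFrameSchedule("1x600,1x300")
  t2 <- Tac(s2, c(2, 5))
  expect_equal(as.numeric(suvValue(t2, c(0, 15), dose = 100, weight = 100)),
               (2 * 10 + 5 * 5) / 15)
  ## invariance to frame subdivision within the window
  s4 <- parseFrameSchedule("4x300")
  expect_equal(as.numeric(suvValue(Tac(s4, rep(3, 4)), c(0, 20), 210, 70)),
               as.numeric(suvValue(tc, c(0, 20), 210, 70)))
  ## the printed schedule is shifted 10 s past nominal, so a 40-50 min
  ## window clips two frames and triggers the partial-frame warning
  expect_warning(suvValue(fixtureTac2t3k, c(40, 50), 200, 75), "partial")
  expect_error(suvValue(tc, c(10, 30), 210, 70), "covered")
})

test_that("parametric maps apply estimators voxel-wise with NaN propagation", {
  n <- nFrames(fixtureSchedule)
  gmP <- c(K1 = 0.45, k2 = 0.5, k3 = 0.05, vB = 0)  # Ki ~ 0.041 < WM block
  gm <- activity(modelTissueCurve("2T3K", gmP, fixtureInput, fixtureSchedule))
  wm <- activity(fixtureTac2t3k)
  vox <- rbind(matrix(rep(wm, 4), nrow = 4, byrow = TRUE),
               matrix(rep(gm, 4), nrow = 4, byrow = TRUE))
  vox <- rbind(vox, NA)
  map <- parametricMap(vox, fixtureSchedule, fixtureInput, method = "mlair2")
  regionEst <- mlair2Fit(fixtureTac2t3k, fixtureInput)@estimate
  expect_equal(map[1], regionEst, tolerance = 1e-10)
  expect_equal(map[1:4], rep(map[1], 4))
  ## block means ordered by the generating Ki (WM above GM for this tracer)
  expect_gt(mean(map[1:4]), mean(map[5:8]))
  expect_true(is.nan(map[9]))
  suv <- parametricMap(vox, fixtureSchedule, method = "suv",
                       interval = c(30, 40), dose = 200, weight = 70)
  expect_true(is.nan(suv[9]))
  expect_gt(suv[1], suv[5])
  expect_error(parametricMap(vox[, 1:10], fixtureSchedule, fixtureInput),
               "matching")
})
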