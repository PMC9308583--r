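lesionRow <- function(flair = TRUE, t1 = "hypointense", gd = FALSE,
                      v1 = 0.1, vf = 0.1, diam = 5) {
  data.frame(flair_hyper = flair, t1_class = t1, gd_hyper = gd,
             vol_t1_ml = v1, vol_flair_ml = vf, max_diam_mm = diam)
}

test_that("lesion classification follows the radiological rule table", {
  expect_equal(as.character(classifyLesion(lesionRow(t1 = "iso_to_NAWM"))),
               "remyelinated")
  expect_equal(as.character(classifyLesion(
    lesionRow(t1 = "hypointense", v1 = 0.05, vf = 0.10))),
    "partially_myelinated")
  expect_equal(as.character(classifyLesion(
    lesionRow(t1 = "hypointense", v1 = 0.095, vf = 0.10))), "demyelinated")
  expect_equal(as.character(classifyLesion(lesionRow(t1 = "iso_to_CSF"))),
               "black_hole")
  ## gadolinium enhancement dominates all tissue-contrast rules
  expect_equal(as.character(classifyLesion(lesionRow(t1 = "iso_to_CSF",
                                                     gd = TRUE))), "active")
  ## the > 3 mm diameter gate is strict and outranks activity
  expect_equal(as.character(classifyLesion(lesionRow(gd = TRUE, diam = 3))),
               "excluded")
  expect_equal(as.character(classifyLesion(lesionRow(diam = 2.9))), "excluded")
  ## inconsistent descriptor: classified by T1 class but flagged
  res <- classifyLesion(lesionRow(flair = FALSE, t1 = "iso_to_CSF"))
  expect_equal(as.character(res), "black_hole")
  expect_true(attr(res, "flagged"))
  expect_error(classifyLesion(lesionRow()[, -1]), "missing")
})

test_that("classification is total and deterministic over the descriptor grid", {
  grid <- expand.grid(flair_hyper = c(TRUE, FALSE),
                      t1_class = c("iso_to_NAWM", "hypointense", "iso_to_CSF"),
                      gd_hyper = c(TRUE, FALSE),
                      vol_t1_ml = c(0.05, 0.095, 0.2),
                      vol_flair_ml = 0.1,
                      max_diam_mm = c(2, 3, 3.01, 8),
                      stringsAsFactors = FALSE)
  got <- classifyLesion(grid)
  expect_false(any(is.na(got)))
  want <- vapply(seq_len(nrow(grid)),
                 function(i) oracleLesionClass(grid[i, ]), character(1))
  expect_equal(as.character(got), want)
  ## every class reachable: the rule table partitions the space
  expect_setequal(unique(want),
                  c("excluded", "active", "black_hole", "demyelinated",
                    "partially_myelinated", "remyelinated"))
})

test_that("reliability filtering removes high-percent-SE estimates", {
  df <- data.frame(sePercent = rep(10, 5), model = "2T3K")
  expect_equal(filterReliable(df)$removedFraction, 0)
  df2 <- data.frame(sePercent = c(10, 30, 20, 40))
  out <- filterReliable(df2)
  expect_equal(out$removedFraction, 0.5)
  expect_equal(nrow(out$kept), 2)
  df3 <- data.frame(sePercent = c(10, 30, 10, 10),
                    model = c("a", "a", "b", "b"))
  byModel <- filterReliable(df3, by = "model")$removedFraction
  expect_equal(byModel$removedFraction[byModel$model == "a"], 0.5)
  expect_equal(byModel$removedFraction[byModel$model == "b"], 0)
})

test_that("model preference tallies lowest-AIC votes with tie splitting", {
  tab <- data.frame(region = rep(c("r1", "r2", "r3"), each = 2),
                    model = rep(c("A", "B"), 3),
                    aic = c(1, 2, 0, 5, -3, -1))
  pref <- modelPreference(tab)
  expect_equal(pref$percent[pref$model == "A"], 100)
  expect_equal(sum(pref$votes), 3)
  tie <- data.frame(region = c("r1", "r1"), model = c("A", "B"), aic = c(1, 1))
  expect_warning(prefT <- modelPreference(tie), "tie")
  expect_equal(prefT$votes, c(0.5, 0.5))
})

test_that("method comparison returns exact Pearson and OLS quantities", {
  x <- c(0.05, 0.08, 0.11, 0.07)
  self <- compareMethods(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$slope, 1)
  expect_equal(self$intercept, 0, tolerance = 1e-12)
  aff <- compareMethods(x, 0.9 * x + 0.01)
  expect_equal(aff$r, 1)
  expect_equal(aff$slope, 0.9)
  expect_equal(aff$intercept, 0.01)
  ## hand-computed toy set
  hand <- compareMethods(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(hand$slope, 1.4)
  expect_equal(hand$r, 7 / sqrt(50), tolerance = 1e-12)  # 0.98995
  expect_error(compareMethods(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(compareMethods(1:2, 1:2), "3")
})

test_that("the gated two-group test reports t, pooled df and p", {
  same <- groupDifference(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_equal(same$df, 6)
  set.seed(2)
  g1 <- c(1, 1, 1) + rnorm(3, 0, 1e-3)
  g2 <- c(2, 2, 2) + rnorm(3, 0, 1e-3)
  sep <- groupDifference(g1, g2)
  expect_lt(sep$p, 0.01)
  ## pooled df when Levene passes
  set.seed(4)
  a <- rnorm(6, 0, 1); b <- rnorm(6, 0.5, 1)
  gd <- groupDifference(a, b)
  if (gd$testUsed == "student") expect_equal(gd$df, 10)
})

test_that("Mann-Whitney matches closed forms and brute-force enumeration", {
  expect_equal(lesionVsNawm(c(1, 2), c(3, 4))$U, 0)
  expect_equal(lesionVsNawm(c(1, 2, 3), c(1, 2, 3))$U, 4.5)  # n1*n2/2
  bf <- bruteForceMannWhitney(c(3, 5, 6), c(4, 7, 8, 9))
  got <- lesionVsNawm(c(3, 5, 6), c(4, 7, 8, 9))
  expect_equal(got$U, bf$U)
  expect_equal(got$p, bf$p)
  ## exhaustive agreement with enumeration across small tie-free samples
  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(1:8, 1); n2 <- sample(1:(10 - n1), 1)
    repeat {
      x <- runif(n1); y <- runif(n2, 0.3, 1.3)
      if (!any(duplicated(c(x, y)))) break
    }
    bf <- bruteForceMannWhitney(x, y)
    got <- lesionVsNawm(x, y)
    expect_equal(got$U, bf$U)
    expect_equal(got$p, bf$p, tolerance = 1e-12)
  }
  ## ties fall back to the corrected normal approximation
  tied <- lesionVsNawm(c(1, 2, 2), c(2, 3, 4))
  expect_equal(tied$method, "normal")
  expect_true(tied$p > 0 && tied$p <= 1)
})
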