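grid8 <- c(-5, 0, 15, 30, 45, 60, 90, 120)

test_that("the fasting baseline is the mean of the t <= 0 samples", {
  expect_equal(baselineGlucose(GlycemicCurve(c(-5, 0, 15), c(5.0, 5.2, 7))),
               5.1)
  expect_equal(baselineGlucose(GlycemicCurve(c(0, 30), c(4.8, 6))), 4.8)
  expect_equal(baselineGlucose(GlycemicCurve(c(-5, 0, 30), c(5, 5, 6))), 5)
})

test_that("IAUC follows the positive-part trapezoid with crossing interpolation", {
  ## hand oracle: peak 2 mmol/L above baseline at 15 min, back at 30
  gc <- GlycemicCurve(c(-5, 0, 15, 30, 45, 60, 90, 120),
                      c(5, 5, 7, 5, 5, 5, 5, 5))
  expect_equal(iauc(gc)$iauc, 30)
  ## constant at baseline
  expect_equal(iauc(GlycemicCurve(grid8, rep(5, 8)))$iauc, 0)
  ## everything below baseline is disregarded
  expect_equal(iauc(GlycemicCurve(grid8, c(5, 5, 4, 4, 4, 4, 4, 4)))$iauc, 0)
  ## crossing segment: only the positive triangle counts
  gc2 <- GlycemicCurve(c(-5, 0, 15, 30), c(5, 5, 7, 3))
  ## rise: 15 min trapezoid = 15; fall crosses at 7.5 min -> 2*7.5/2 = 7.5
  expect_equal(iauc(gc2)$iauc, 15 + 7.5)
  expect_error(iauc(GlycemicCurve(c(-5, 0), c(5, 5))), "at least two")
})

test_that("IAUC matches a dense quadrature oracle to < 0.1 %", {
  set.seed(8)
  for (rep in 1:20) {
    g <- 5 + c(0, 0, cumsum(rnorm(6, 0, 1.2)))
    g <- pmax(g, 3.5)
    oracle <- iaucOracle(grid8, g)
    got <- iauc(GlycemicCurve(grid8, g))$iauc
    if (oracle > 1e-6) expect_lt(abs(got - oracle) / oracle, 0.001)
    else expect_lt(abs(got - oracle), 1e-6)
  }
})

test_that("IAUC is invariant to adding a constant to the whole curve", {
  g <- c(5, 5.2, 7.4, 8.1, 7.0, 6.2, 5.4, 5.2)
  a <- iauc(GlycemicCurve(grid8, g))$iauc
  b <- iauc(GlycemicCurve(grid8, g + 2.5))$iauc
  expect_equal(a, b)
})

test_that("GI is the reference-normalized IAUC and is scale-free", {
  expect_equal(subjectGi(30, c(30, 30, 30)), 100)
  expect_equal(subjectGi(15, c(30, 30, 30)), 50)
  expect_equal(subjectGi(0, c(30, 30, 30)), 0)
  expect_error(subjectGi(10, numeric(0)), "reference")
  expect_error(subjectGi(10, c(0, 0)), "non-responder")
  ## scaling all excursions by c leaves the GI unchanged
  b <- 5; g <- c(5, 5, 7.5, 8.5, 7.2, 6.4, 5.6, 5.2)
  for (cc in c(0.5, 2, 3)) {
    test <- iauc(GlycemicCurve(grid8, b + (g - b) * 0.6))$iauc
    ref <- iauc(GlycemicCurve(grid8, g))$iauc
    testC <- iauc(GlycemicCurve(grid8, b + (g - b) * 0.6 * cc))$iauc
    refC <- iauc(GlycemicCurve(grid8, b + (g - b) * cc))$iauc
    expect_equal(testC, cc * test)
    expect_equal(100 * testC / refC, 100 * test / ref)
  }
})

test_that("GI classification uses <=55 low, >=70 high, else medium", {
  expect_equal(classifyGi(49.15), "low")    # lowest published variety
  expect_equal(classifyGi(92.31), "high")   # highest published variety
  expect_equal(classifyGi(55.0), "low")
  expect_equal(classifyGi(55.5), "medium")
  expect_equal(classifyGi(69.5), "medium")
  expect_equal(classifyGi(70.0), "high")
  expect_error(classifyGi(-1))
})

test_that("study GI is the subject mean with sample sd and class", {
  tr <- studyGi(c(50, 50, 50))
  expect_equal(giMean(tr), 50)
  expect_equal(giSd(tr), 0)
  expect_equal(giClass(tr), "low")
  one <- studyGi(80)
  expect_equal(giMean(one), 80)
  expect_true(is.na(giSd(one)))
  expect_error(studyGi(numeric(0)), "at least one")
})

test_that("the long-format pipeline recovers programmed GI exactly without noise", {
  sim <- simulateGlycemicCurves(c(foodA = 45, foodB = 80), nSubjects = 6,
                                noiseSd = 0, seed = 17)
  out <- giTable(sim$curves)
  expect_equal(out$gi_mean[out$food_id == "foodA"], 45, tolerance = 1e-10)
  expect_equal(out$gi_mean[out$food_id == "foodB"], 80, tolerance = 1e-10)
  expect_equal(out$gi_class, c("low", "high"))
  expect_equal(out$n_subjects, c(6, 6))
})

test_that("curves with missing samples or bad grids are rejected", {
  expect_error(GlycemicCurve(c(-5, 0, 15), c(5, NA, 6)), "missing")
  expect_error(GlycemicCurve(c(0, 0, 15), c(5, 5, 6)))
  expect_error(GlycemicCurve(c(15, 30), c(5, 6)))  # no fasting sample
  expect_error(GlycemicCurve(c(-5, 0), c(5, -1)))
})
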