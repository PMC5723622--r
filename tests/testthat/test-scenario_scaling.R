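test_that("scaling patterns divide the change field by the global warming", {
  base <- tinyGrid(matrix(10, 4, 3))
  fut <- tinyGrid(matrix(10 + 3.49, 4, 3), period = "future")
  p <- computeScalingPattern(base, fut, 3.49)
  expect_equal(unique(as.vector(gridValues(p))), 1.0)
  expect_equal(globalDT(p), 3.49)
  p0 <- computeScalingPattern(base, base, 3.49)
  expect_equal(unique(as.vector(gridValues(p0))), 0)
  expect_error(computeScalingPattern(base, fut, 0), "positive")
  expect_error(
    computeScalingPattern(base, tinyGrid(matrix(1, 5, 3)), 3.49),
    "geometry"
  )
})

test_that("pattern scaling round-trips the future grid algebraically", {
  set.seed(81)
  for (i in 1:20) {
    v <- matrix(rnorm(20, 10), 4, 5)
    f <- v + matrix(rnorm(20, 2), 4, 5)
    base <- tinyGrid(v)
    fut <- tinyGrid(f, period = "future")
    dT <- runif(1, 2, 5)
    p <- computeScalingPattern(base, fut, dT)
    expect_equal(gridValues(p) * dT + v, f)
  }
})

test_that("scenarios are exact at the offset and affine in X", {
  set.seed(82)
  base <- tinyGrid(matrix(rnorm(12, 10), 4, 3))
  pat <- computeScalingPattern(
    base, tinyGrid(gridValues(base) + matrix(runif(12, 1, 3), 4, 3)), 3.5
  )
  s05 <- buildScenario(base, pat, 0.5)
  expect_identical(gridValues(s05), gridValues(base))  # bit-exact
  ones <- computeScalingPattern(base, tinyGrid(gridValues(base) + 1), 1)
  s4 <- buildScenario(base, ones, 4.0)
  expect_equal(gridValues(s4), gridValues(base) + 3.5)
  s20 <- buildScenario(base, pat, 2.0)
  s15 <- buildScenario(base, pat, 1.5)
  expect_equal(gridValues(s20) - gridValues(s15), 0.5 * gridValues(pat))
})

test_that("the four ensemble divisors round-trip their future grids", {
  # X = globalDT + offset inflates the pattern by exactly globalDT
  for (dT in c(3.49, 3.57, 3.50, 3.41)) {
    w <- makeGridWorld(warming = c(1.5, 3.2), globalDT = dT, seed = 6L)
    p <- computeScalingPattern(w$present$temp_mean, w$future$temp_mean, dT)
    rebuilt <- buildScenario(w$present$temp_mean, p, dT + 0.5)
    expect_equal(gridValues(rebuilt), gridValues(w$future$temp_mean))
  }
})

test_that("masked cells never acquire values through scaling operations", {
  w <- makeGridWorld(warming = 2, maskFraction = 0.25, seed = 9L)
  p <- computeScalingPattern(w$present$temp_mean, w$future$temp_mean, 3.49)
  m <- gridMask(w$present$temp_mean)
  expect_true(all(is.na(gridValues(p)[!m])))
  scen <- buildScenario(w$present$temp_mean, p, 3.0)
  expect_true(all(is.na(gridValues(scen)[!m])))
})

test_that("running means agree exactly with naive window sums", {
  expect_equal(runningMean(rep(3, 30), 20), rep(3, 11))
  lin <- seq(2, 60, by = 2)
  rm20 <- runningMean(lin, 20, years = seq_along(lin))
  expect_equal(rm20$value, lin[1:11] + 19)  # linear: value at window centre
  expect_equal(rm20$year, 1:11 + 9.5)
  set.seed(91)
  for (i in 1:60) {
    n <- sample(25:80, 1)
    w <- sample(2:20, 1)
    x <- rnorm(n)
    naive <- vapply(seq_len(n - w + 1),
                    function(j) sum(x[j:(j + w - 1)]) / w, numeric(1))
    expect_identical(runningMean(x, w), naive)
  }
  expect_error(runningMean(1:5, 20), "window")
})

test_that("exceedance years honour the preindustrial offset", {
  s <- makeAnomalySeries(rate = 0.02)
  expect_equal(exceedanceYear(s, 1.5), 2040)  # anomaly 1.0 = 1.5 - 0.5
  expect_equal(exceedanceYear(s, 0.5), 1990)
  xs <- c(0.5, 1.0, 1.5, 2.0)
  yrs <- vapply(xs, function(X) exceedanceYear(s, X), numeric(1))
  expect_true(all(diff(yrs) >= 0))
  expect_message(big <- exceedanceYear(s, 4.0), "not exceeded")
  expect_true(is.na(big))
  expect_error(exceedanceYear(s, 0.2), "offset")
})

test_that("bias correction matches the observed reference per cell", {
  set.seed(92)
  obs <- tinyGrid(matrix(rnorm(12, 10), 4, 3))
  expect_equal(gridValues(biasCorrect(obs, obs)), gridValues(obs))
  warm <- tinyGrid(gridValues(obs) + 2)
  expect_equal(gridValues(biasCorrect(warm, obs)), gridValues(obs))
  biased <- tinyGrid(gridValues(obs) + matrix(rnorm(12), 4, 3))
  expect_equal(gridValues(biasCorrect(biased, obs)), gridValues(obs))
  # radiation: multiplicative with a near-zero guard
  simR <- tinyGrid(matrix(c(0, rep(5, 11)), 4, 3), variable = "radiation")
  obsR <- tinyGrid(matrix(14, 4, 3), variable = "radiation")
  expect_warning(corr <- biasCorrect(simR, obsR), "guard")
  v <- gridValues(corr)
  expect_equal(v[gridValues(simR) == 5][1], 14)
  expect_equal(v[gridValues(simR) == 0], 0)  # guarded cell left alone
})
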