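test_that("grid prediction matches pointwise logistic evaluation", {
  g <- tinyGrid(matrix(seq(-2, 2, length.out = 12), 4, 3),
                variable = "temperature")
  zero <- manualModel(c(`(Intercept)` = 0, x = 0))
  p <- predictGrid(zero, list(x = g))
  expect_equal(unique(as.vector(gridValues(p))), 0.5)
  b0 <- manualModel(c(`(Intercept)` = 1.2))
  p0 <- predictGrid(b0, list(x = g))
  expect_equal(unique(as.vector(gridValues(p0))), plogis(1.2))
  m <- manualModel(c(`(Intercept)` = -3, x = 2))
  p2 <- predictGrid(m, list(x = g))
  # single-cell cross-check against the scalar model
  expect_equal(gridValues(p2)[2, 3],
               unname(predict(m, data.frame(x = gridValues(g)[2, 3]))))
  expect_error(predictGrid(m, list(wrong = g)), "missing predictor")
})

test_that("thresholding is inclusive and respects sentinels", {
  p <- tinyGrid(matrix(c(0.606, 0.605, 0.7, 0.1), 2, 2),
                variable = "probability")
  h <- thresholdMap(p, 0.606)
  expect_equal(gridValues(h)[1, 1], 1)  # equality counts as habitat
  expect_equal(gridValues(h)[2, 1], 0)
  empty <- thresholdMap(p, 1 + 1e-9)
  expect_true(all(gridValues(empty) == 0))
  set.seed(101)
  r <- tinyGrid(matrix(runif(30), 5, 6), variable = "probability")
  expect_equal(gridValues(thresholdMap(r, 0.4)),
               (gridValues(r) >= 0.4) * 1)
})

test_that("habitat fractions count cells inside the region mask", {
  all1 <- tinyGrid(matrix(1, 4, 4), variable = "habitat")
  expect_equal(habitatFraction(all1, latMin = 0, lonMin = 0), 1)
  chk <- tinyGrid(outer(1:4, 1:4, function(i, j) (i + j) %% 2),
                  variable = "habitat")
  expect_equal(habitatFraction(chk, latMin = 0, lonMin = 0), 0.5)
  expect_error(habitatFraction(all1, latMin = 90), "empty region")
  # inclusive bounds: a cell exactly at the boundary is inside
  oneCell <- tinyGrid(matrix(1, 1, 1), latStart = 35, lonStart = 136)
  expect_equal(habitatFraction(oneCell), 1)
})

test_that("northern limits and shifts use cell-centre latitudes", {
  g <- tinyGrid(matrix(0, 5, 2), latStart = 40.0, res = 0.5,
                variable = "habitat")
  v <- gridValues(g)
  v[3, 1] <- 1  # lat 41.0
  g1 <- tinyGrid(v, latStart = 40.0, res = 0.5, variable = "habitat")
  expect_equal(northernLimit(g1), 41.0)
  expect_equal(northwardShift(41.0, 43.25), 2.25 * 111.2)
  expect_equal(northwardShift(41.0, 41.0), 0)
  expect_message(nl <- northernLimit(g), "no habitat")
  expect_true(is.na(nl))
})

test_that("MESS follows the percentile definition and flags novelty", {
  ref <- data.frame(x = c(1, 2, 3, 4))  # median 2.5 has f exactly 50
  g <- tinyGrid(matrix(c(2.5, 0.5, 4.5, 1), 2, 2), variable = "x")
  ms <- messSurface(list(x = g), ref)
  s <- ms@similarity
  expect_equal(s[1, 1], 100)          # at the median
  expect_lt(s[2, 1], 0)               # below the reference minimum
  expect_lt(s[1, 2], 0)               # above the reference maximum
  expect_equal(s[2, 2], 100 * (1 - 1) / 3 + 2 * 0)  # at the minimum: f = 0
  # novelty iff outside the reference range
  expect_true(all((s < 0) == (gridValues(g) < 1 | gridValues(g) > 4)))
})

test_that("MESS equals the brute-force percentile oracle cell by cell", {
  set.seed(111)
  ref <- data.frame(a = rnorm(145, 10, 2), b = runif(145, 12, 16))
  ga <- tinyGrid(matrix(rnorm(40, 10, 4), 5, 8), variable = "a")
  gb <- tinyGrid(matrix(runif(40, 10, 18), 5, 8), variable = "b")
  ms <- messSurface(list(a = ga, b = gb), ref)
  for (i in 1:5) for (j in 1:8) {
    sa <- messBrute(gridValues(ga)[i, j], ref$a)
    sb <- messBrute(gridValues(gb)[i, j], ref$b)
    expect_equal(ms@similarity[i, j], min(sa, sb))
    expect_equal(ms@mdvIndex[i, j], which.min(c(sa, sb)))
  }
})

test_that("degenerate single-valued references are flagged, not fatal", {
  ref <- data.frame(x = c(7, 7, 7))
  g <- tinyGrid(matrix(c(7, 8), 1, 2), variable = "x")
  expect_warning(ms <- messSurface(list(x = g), ref), "degenerate")
  expect_equal(ms@similarity[1, 1], 100)
  expect_equal(ms@similarity[1, 2], 0)
})

test_that("projection reports are monotone in warming for beta_T > 0", {
  st <- summarizeStations(makeStations())
  m <- fitNicheModel(st[c("temp_mean", "radiation")], st$presence)
  w <- makeGridWorld(warming = 2.0, globalDT = 3.49, seed = 7L,
                     resolution = 0.5)
  pats <- list(
    a = lapply(c(temp_mean = "temp_mean", radiation = "radiation"),
               function(nm) computeScalingPattern(w$present[[nm]],
                                                  w$future[[nm]], 3.49)),
    b = lapply(c(temp_mean = "temp_mean", radiation = "radiation"),
               function(nm) computeScalingPattern(w$present[[nm]],
                                                  w$future[[nm]], 3.49))
  )
  rep <- projectReport(m, 0.606, w$present, pats,
                       reference = st[c("temp_mean", "radiation")])
  base <- rep[rep$warming_X == 0.5, ]
  expect_equal(base$shift_km, 0)
  for (mem in c("a", "b")) {
    fr <- rep$fraction[rep$member == mem | rep$warming_X == 0.5]
    expect_true(all(diff(fr) >= 0))
  }
  # identical members give a zero across-member range
  rng <- attr(rep, "range")
  expect_equal(rng$fraction_min, rng$fraction_max)
  # the X = 0.5 row is exactly the current-climate projection
  hab <- thresholdMap(predictGrid(m, w$present), 0.606)
  expect_equal(base$fraction, habitatFraction(hab))
})
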