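test_that("intercept-only fit returns the log-odds of the class balance", {
  y <- rep(c(1, 0), c(116, 29))
  m <- fitNicheModel(data.frame()[seq_along(y), , drop = FALSE], y)
  expect_equal(unname(coef(m)), log(116 / 29), tolerance = 1e-7)
  expect_equal(m@kParams, 1L)
})

test_that("a pure-noise predictor has a slope within 3 SE of zero", {
  set.seed(21)
  n <- 10000
  x <- data.frame(noise = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  m <- fitNicheModel(x, y)
  se <- sqrt(diag(vcov(m)))["noise"]
  expect_lt(abs(coef(m)["noise"]), 3 * se)
})

test_that("true synthetic-world coefficients are recovered at n = 5000", {
  st <- makeStations(syntheticWorldSpec(nStations = 5000, seed = 17L))
  st <- summarizeStations(st)
  truth <- attr(st, "trueCoefficients")
  m <- fitNicheModel(st[c("temp_mean", "radiation")], st$presence)
  se <- sqrt(diag(vcov(m)))
  expect_true(all(abs(coef(m) - truth) < 3 * se))
})

test_that("degenerate designs raise structured errors", {
  y <- rep(0:1, 20)
  expect_error(fitNicheModel(data.frame(flat = rep(2, 40)), y),
               "zero-variance.*flat")
  x <- data.frame(a = rnorm(40))
  x$b <- 2 * x$a
  expect_error(fitNicheModel(x, y), "rank-deficient")
  expect_error(fitNicheModel(data.frame(a = rnorm(3)), c(0, 1, 2)),
               "binary")
})

test_that("complete separation is flagged with the offending predictor", {
  x <- data.frame(temp = c(-5:-1, 1:5), other = rnorm(10, sd = 1e-3))
  y <- as.numeric(x$temp > 0)
  err <- tryCatch(fitNicheModel(x, y), error = identity)
  expect_s3_class(err, "bambooclim_separation")
  expect_match(conditionMessage(err), "temp")
})

test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-40, 3, 145), 86 + 24 / 141)
  expect_equal(aicc(-40, 3, 1e9), 86, tolerance = 1e-6)
  expect_equal(aicc(-40, 0, 145), 80)
  expect_error(aicc(-40, 144, 145), "exceed")
  # strictly decreasing in logLik, strictly increasing in k (n > k + 2)
  expect_lt(aicc(-39, 3, 145), aicc(-40, 3, 145))
  expect_gt(aicc(-40, 4, 145), aicc(-40, 3, 145))
})

test_that("dredge enumerates every subset and ranks by AICc", {
  set.seed(31)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$presence <- rbinom(n, 1, plogis(1.5 * d$x1))
  tab <- dredgeSubsets(d, terms = c("x1", "x2"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$deltaAICc[1], 0)
  expect_true(all(diff(tab$AICc[tab$converged]) >= 0))
  d4 <- cbind(d, x3 = rnorm(n), x4 = rnorm(n))
  expect_equal(nrow(dredgeSubsets(d4, terms = c("x1", "x2", "x3", "x4"))),
               16L)
})

test_that("dredge prefers the true predictor over pure noise", {
  set.seed(32)
  n <- 5000
  d <- data.frame(signal = rnorm(n), noise = rnorm(n))
  d$presence <- rbinom(n, 1, plogis(1.2 * d$signal))
  tab <- dredgeSubsets(d, terms = c("noise", "signal"))
  expect_match(tab$terms[1], "signal")
})

test_that("the pooled ten-global-model recipe returns a coherent ranking", {
  st <- summarizeStations(makeStations(syntheticWorldSpec(seed = 12L)))
  ranked <- rankGlobalModels(st)
  expect_equal(ranked$deltaAICc[1], 0)
  expect_false(any(duplicated(ranked$terms)))
  # with temperature driving the truth, some temperature variable must
  # appear in the AICc-best term set (all five are near-collinear)
  expect_match(ranked$terms[1], "temp_mean|tmin_year|tmax_year|wi|ci")
})

test_that("LOOCV scores records out-of-fold, in input order", {
  set.seed(41)
  n <- 60
  x <- data.frame(t = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x$t))
  s <- loocvScores(x, y)
  expect_length(s, n)
  # fold i must not see record i: recompute fold 1 by hand
  m1 <- fitNicheModel(x[-1, , drop = FALSE], y[-1])
  expect_equal(s[1], unname(predict(m1, x[1, , drop = FALSE])))
  # permutation equivariance
  p <- sample(n)
  expect_equal(loocvScores(x[p, , drop = FALSE], y[p]), s[p])
  expect_error(loocvScores(x[1:2, , drop = FALSE], y[1:2]), "at least 3")
})

test_that("LOOCV AUC tracks resubstitution AUC on well-separated data", {
  st <- summarizeStations(makeStations(syntheticWorldSpec(
    nStations = 300, seed = 13L,
    trueCoefficients = c(-36, 4, 0.15))))
  x <- st[c("temp_mean", "radiation")]
  m <- fitNicheModel(x, st$presence)
  resub <- rocAuc(predict(m, x), st$presence)
  cv <- suppressWarnings(loocvScores(x, st$presence))
  expect_lt(abs(rocAuc(cv, st$presence) - resub), 0.02)
})

test_that("AUC equals its pairwise and trapezoid oracles", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(rocAuc(s, y), aucPairwise(s, y))
    expect_equal(rocAuc(s, y), aucTrapezoid(s, y))
  }
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  s <- runif(80)
  y <- rbinom(80, 1, s)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s))))
  expect_equal(rocAuc(s, y), ref)
})

test_that("Youden threshold equals the exhaustive candidate scan", {
  got <- youdenThreshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(got$threshold, 0.5)
  expect_equal(got$J, 1)
  flat <- youdenThreshold(rep(0.4, 8), rep(c(1, 0), 4))
  expect_equal(flat$J, 0)
  expect_equal(flat$threshold, -Inf)  # degenerate: predict all present
  set.seed(61)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    s <- round(runif(n), 2)
    y <- c(0, 1, rbinom(n - 2, 1, 0.6))
    expect_identical(youdenThreshold(s, y), youdenBrute(s, y))
  }
})

test_that("confusion counts honour the inclusive >= rule and sentinels", {
  s <- c(0.9, 0.7, 0.6, 0.3, 0.2)
  y <- c(1, 1, 0, 0, 1)
  expect_equal(confusionCounts(s, y, -Inf),
               c(TP = 3, FP = 2, FN = 0, TN = 0))
  expect_equal(confusionCounts(s, y, Inf),
               c(TP = 0, FP = 0, FN = 3, TN = 2))
  expect_equal(confusionCounts(s, y, 0.6),
               c(TP = 2, FP = 1, FN = 1, TN = 1))
})

test_that("metrics reproduce the printed worked example to 3 dp", {
  counts <- c(TP = 112, FP = 6, FN = 4, TN = 23)
  m <- classificationMetrics(counts)
  expect_equal(round(m$mcc, 3), 0.780)
  expect_equal(round(m$informedness, 3), 0.759)
  expect_equal(round(m$accuracy, 3), 0.931)
})

test_that("metrics behave under perfection, label flips, and empty margins", {
  perfect <- classificationMetrics(c(TP = 10, FP = 0, FN = 0, TN = 10))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  a <- classificationMetrics(c(TP = 8, FP = 3, FN = 2, TN = 7))
  flip <- classificationMetrics(c(TP = 2, FP = 7, FN = 8, TN = 3))
  expect_equal(flip$mcc, -a$mcc)
  expect_equal(flip$informedness, -a$informedness)
  w <- capture_warnings(
    und <- classificationMetrics(c(TP = 0, FP = 0, FN = 5, TN = 5))
  )
  expect_true(any(grepl("PPV undefined", w)))
  expect_true(any(grepl("MCC undefined", w)))
  expect_true(is.na(und$ppv))
  expect_false(isTRUE(und$ppv == 0))
})

test_that("printed metrics invert to a unique confusion matrix", {
  expect_equal(solveConfusion(116, 29, 0.931, 0.759),
               c(TP = 112, FP = 6, FN = 4, TN = 23))
  expect_equal(solveConfusion(10, 10, 1.0, 1.0),
               c(TP = 10, FP = 0, FN = 0, TN = 10))
  expect_error(solveConfusion(10, 10, 0.0, 1.0), "no integer")
})

test_that("collinearity screen flags duplicates and sign flips only", {
  x <- data.frame(a = rnorm(100))
  x$dup <- x$a
  x$neg <- -x$a
  sc <- collinearityScreen(x)
  expect_true(all(sc$flagged))
  expect_equal(sc$r[sc$var1 == "a" & sc$var2 == "dup"], 1)
  expect_equal(sc$r[sc$var1 == "a" & sc$var2 == "neg"], -1)
  set.seed(71)
  indep <- as.data.frame(matrix(rnorm(10000 * 3), ncol = 3))
  expect_false(any(collinearityScreen(indep)$flagged))
  withZero <- data.frame(a = rnorm(50), z = rep(1, 50))
  sz <- collinearityScreen(withZero)
  expect_true(all(sz$flagged[is.na(sz$r)]))
})
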