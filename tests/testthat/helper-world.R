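# shared fixtures built in code

# a tiny all-land grid with prescribed values
tinyGrid <- function(values, latStart = 35.25, lonStart = 136.25, res = 0.5,
                     variable = "temperature", period = "present") {
  values <- as.matrix(values)
  climateGrid(values,
              lat = latStart + res * (seq_len(nrow(values)) - 1),
              lon = lonStart + res * (seq_len(ncol(values)) - 1),
              variable = variable, period = period)
}

# random monthly climatology (temperatures may straddle the 5 degC line)
randomClimatology <- function() {
  list(temp = stats::runif(12, -5, 25),
       precip = stats::runif(12, 0, 300))
}

# a intercept-free logit model object with chosen coefficients, for
# grid-prediction tests that need exact known truth
manualModel <- function(coefs) {
  k <- length(coefs)
  new("FittedNicheModel",
      predictorNames = names(coefs)[-1],
      coefficients = coefs,
      vcov = diag(k),
      logLik = 0, nObs = 10L, kParams = as.integer(k),
      aicc = NA_real_, converged = TRUE, separation = FALSE)
}

# brute-force AUC over all presence/absence pairs (O(n^2) oracle)
aucPairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# trapezoidal integral under the empirical ROC curve (independent oracle)
aucTrapezoid <- function(scores, labels) {
  y <- as.numeric(labels)
  taus <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(taus))
  for (i in seq_along(taus)) {
    pred <- scores >= taus[i]
    sens[i] <- sum(pred & y == 1) / sum(y == 1)
    spec[i] <- sum(!pred & y == 0) / sum(y == 0)
  }
  fpr <- 1 - spec
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

# exhaustive Youden scan over every candidate threshold
youdenBrute <- function(scores, labels) {
  y <- as.numeric(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- list(threshold = NA_real_, J = -Inf)
  for (tau in cand) {
    pred <- scores >= tau
    j <- sum(pred & y == 1) / sum(y == 1) +
      sum(!pred & y == 0) / sum(y == 0) - 1
    if (j > best$J) best <- list(threshold = tau, J = j)
  }
  best
}

# per-cell MESS oracle, straight from the percentile definition
messBrute <- function(v, ref) {
  n <- length(ref)
  rmin <- min(ref); rmax <- max(ref)
  f <- 100 * sum(ref < v) / n
  if (f == 0) {
    100 * (v - rmin) / (rmax - rmin)
  } else if (f <= 50) {
    2 * f
  } else if (f < 100) {
    2 * (100 - f)
  } else {
    100 * (rmax - v) / (rmax - rmin)
  }
}
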