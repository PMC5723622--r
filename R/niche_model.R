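#' Fit a binomial-logit niche model
#'
#' Fits presence/absence against a predictor table by maximum likelihood
#' with a logit link (via iteratively reweighted least squares, relative
#' log-likelihood tolerance 1e-8, at most 100 iterations). Complete
#' separation is detected and raised as an error of class
#' `"bambooclim_separation"` naming the most implicated predictor;
#' rank-deficient designs are rejected.
#'
#' @param predictors data.frame or numeric matrix of predictor columns
#'   (the intercept is added internally); may have zero columns for an
#'   intercept-only model.
#' @param response binary vector (0/1 or logical), one per row.
#' @return a [FittedNicheModel-class].
#' @examples
#' fitNicheModel(data.frame()[rep(1, 145), , drop = FALSE],
#'               rep(c(1, 0), c(116, 29)))  # intercept = log(116/29)
#' @export
fitNicheModel <- function(predictors, response) {
  x <- as.data.frame(predictors)
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) {
    stop("'response' must be binary (0/1)", call. = FALSE)
  }
  if (nrow(x) > 0 && nrow(x) != length(y)) {
    stop("'predictors' and 'response' lengths differ", call. = FALSE)
  }
  if (ncol(x) > 0) {
    sds <- vapply(x, stats::sd, numeric(1))
    if (any(sds == 0 | is.na(sds))) {
      stop("zero-variance predictor: ",
           paste(names(x)[sds == 0 | is.na(sds)], collapse = ", "),
           call. = FALSE)
    }
  }
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    xm, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  mu <- fit$fitted.values
  eps <- 1e-6
  separated <- ncol(x) > 0 && all(mu[y == 1] > 1 - eps) &&
    all(mu[y == 0] < eps)
  if (separated) {
    # implicate the predictor whose standardized effect is largest
    std <- abs(fit$coefficients[-1]) * vapply(x, stats::sd, numeric(1))
    offender <- names(x)[which.max(std)]
    cond <- structure(
      class = c("bambooclim_separation", "error", "condition"),
      list(message = paste0(
        "complete separation detected; coefficients diverge (predictor: ",
        offender, ")"), call = NULL)
    )
    stop(cond)
  }
  beta <- fit$coefficients
  eta <- drop(xm %*% beta)
  # log(1 + e^eta) in overflow-safe form
  ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                             log1p(exp(eta))))
  w <- mu * (1 - mu)
  info <- crossprod(xm * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(xm), ncol(xm))
  })
  dimnames(vc) <- list(colnames(xm), colnames(xm))
  k <- ncol(xm)
  n <- length(y)
  new("FittedNicheModel",
      predictorNames = colnames(xm)[-1],
      coefficients = beta,
      vcov = vc,
      logLik = ll,
      nObs = as.integer(n),
      kParams = as.integer(k),
      aicc = if (n - k - 1 > 0) aicc(ll, k, n) else NA_real_,
      converged = isTRUE(fit$converged),
      separation = FALSE)
}

#' Predict presence probability for new data
#'
#' @param object a [FittedNicheModel-class].
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... ignored.
#' @return vector of presence probabilities.
#' @export
setMethod("predict", "FittedNicheModel", function(object, newdata, ...) {
  miss <- setdiff(object@predictorNames, names(newdata))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  xm <- cbind(1, as.matrix(newdata[object@predictorNames]))
  stats::plogis(drop(xm %*% object@coefficients))
})

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; defined only when
#' `n > k + 1`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (including the intercept).
#' @param n number of observations.
#' @return the AICc value.
#' @examples
#' aicc(-40, 3, 145)  # 86 + 24/141
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model comparison
#'
#' Fits every subset of the candidate terms (including the intercept-only
#' model) to the data and ranks the fits by AICc, the selection protocol of
#' classical information-theoretic niche modelling. Subsets that fail to
#' converge or separate are retained with a status flag but excluded from
#' the ranking. Ties in AICc are broken by fewer parameters, then by
#' lexicographic term order.
#'
#' @param data data.frame with the candidate predictor columns and the
#'   response.
#' @param response name of the binary response column.
#' @param terms character vector of candidate predictor columns (at most
#'   20).
#' @return data.frame with columns `terms` (`+`-joined, `"1"` for the
#'   intercept-only model), `k`, `logLik`, `AICc`, `deltaAICc`, `converged`,
#'   ranked models first (ascending AICc), failed fits last with `NA` AICc.
#' @export
dredgeSubsets <- function(data, response = "presence", terms) {
  if (length(terms) > 20) {
    stop("at most 20 candidate terms are supported", call. = FALSE)
  }
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- data[[response]]
  subsets <- lapply(0:(2^length(terms) - 1), function(bits) {
    terms[bitwAnd(bits, 2^(seq_along(terms) - 1)) > 0]
  })
  rows <- lapply(subsets, function(tt) {
    fit <- tryCatch(
      fitNicheModel(data[, tt, drop = FALSE], y),
      error = function(e) e
    )
    label <- if (length(tt)) paste(sort(tt), collapse = " + ") else "1"
    if (inherits(fit, "error")) {
      data.frame(terms = label, k = length(tt) + 1L, logLik = NA_real_,
                 AICc = NA_real_, converged = FALSE)
    } else {
      data.frame(terms = label, k = fit@kParams, logLik = fit@logLik,
                 AICc = fit@aicc, converged = fit@converged)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$AICc)
  ranked <- tab[ok, ]
  ranked <- ranked[order(ranked$AICc, ranked$k, ranked$terms), ]
  ranked$deltaAICc <- ranked$AICc - min(ranked$AICc)
  failed <- tab[!ok, ]
  if (nrow(failed)) failed$deltaAICc <- NA_real_
  out <- rbind(ranked, failed)
  rownames(out) <- NULL
  out[c("terms", "k", "logLik", "AICc", "deltaAICc", "converged")]
}

#' Two-stage global-model selection recipe
#'
#' Reproduces the classical two-stage protocol for collinear climatologies:
#' ten global models are formed by crossing five temperature-related
#' variables with two precipitation variables (each global model also
#' carrying non-growing-season precipitation, sun radiation, and forest and
#' farmland ratios); each global model is dredged by all-subsets AICc; and
#' the union of the ten rankings is pooled, deduplicated by term set, and
#' re-ranked by AICc.
#'
#' @param data station table with summary columns (see
#'   [summarizeStations()]) and land-use ratios.
#' @param response binary response column name.
#' @param temperatureVars,precipVars,commonVars the variable groups; the
#'   defaults are the standard column names of this package.
#' @return pooled ranked data.frame as in [dredgeSubsets()].
#' @export
rankGlobalModels <- function(data, response = "presence",
                             temperatureVars = c("temp_mean", "tmin_year",
                                                 "tmax_year", "wi", "ci"),
                             precipVars = c("precip_annual",
                                            "precip_growing"),
                             commonVars = c("precip_nongrowing", "radiation",
                                            "forest", "farmland")) {
  pooled <- list()
  for (i in temperatureVars) {
    for (j in precipVars) {
      pooled[[paste(i, j)]] <-
        dredgeSubsets(data, response, c(i, j, commonVars))
    }
  }
  tab <- do.call(rbind, pooled)
  tab <- tab[!duplicated(tab$terms), ]
  ok <- tab$converged & is.finite(tab$AICc)
  ranked <- tab[ok, ]
  ranked <- ranked[order(ranked$AICc, ranked$k, ranked$terms), ]
  ranked$deltaAICc <- ranked$AICc - min(ranked$AICc)
  failed <- tab[!ok, ]
  out <- rbind(ranked, failed)
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated presence scores
#'
#' Scores every record with a model fitted on all other records. Folds in
#' which the reduced data separate or fail to converge are scored `NA`
#' with a warning (rare-absence data can separate in folds) and should be
#' excluded downstream.
#'
#' @inheritParams fitNicheModel
#' @return numeric vector of out-of-fold presence probabilities, in input
#'   order.
#' @export
loocvScores <- function(predictors, response) {
  x <- as.data.frame(predictors)
  y <- as.numeric(response)
  n <- length(y)
  if (n < 3) stop("LOOCV needs at least 3 records", call. = FALSE)
  scores <- rep(NA_real_, n)
  bad <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fitNicheModel(x[-i, , drop = FALSE], y[-i]),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      bad <- bad + 1L
    } else {
      scores[i] <- predict(fit, x[i, , drop = FALSE])
    }
  }
  if (bad > 0) {
    warning(bad, " LOOCV fold(s) failed to converge; scored as NA",
            call. = FALSE)
  }
  scores
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected rank statistic (Mann-Whitney):
#' `P(score+ > score-) + 0.5 P(score+ == score-)`.
#'
#' @param scores numeric scores (higher = more presence-like).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  y <- as.numeric(labels)[keep]
  nPos <- sum(y == 1)
  nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# candidate thresholds: midpoints between consecutive sorted unique scores,
# plus -Inf/+Inf sentinels
youdenCandidates <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

#' Youden-optimal classification threshold
#'
#' Chooses the probability cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1` under the inclusive rule
#' "predict presence iff score >= tau", a standard choice for imbalanced
#' presence/absence data. Candidates are the midpoints between consecutive
#' sorted unique scores plus -Inf/+Inf sentinels; ties in J are broken by
#' the smallest threshold (favouring sensitivity).
#'
#' @inheritParams rocAuc
#' @return list with elements `threshold` and `J`.
#' @export
youdenThreshold <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  y <- as.numeric(labels)[keep]
  nPos <- sum(y == 1)
  nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  cand <- youdenCandidates(scores)
  j <- vapply(cand, function(tau) {
    pred <- scores >= tau
    sum(pred & y == 1) / nPos + sum(!pred & y == 0) / nNeg - 1
  }, numeric(1))
  best <- which(j == max(j))[1]  # candidates ascending: first = smallest tau
  list(threshold = cand[best], J = j[best])
}

#' Confusion counts under a threshold
#'
#' @inheritParams rocAuc
#' @param tau threshold; presence predicted iff `score >= tau` (inclusive).
#'   `-Inf`/`+Inf` sentinels allowed.
#' @return named integer vector `c(TP, FP, FN, TN)`; records with `NA`
#'   scores are dropped.
#' @export
confusionCounts <- function(scores, labels, tau) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  y <- as.numeric(labels)[keep]
  pred <- scores >= tau
  c(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
    FN = sum(!pred & y == 1), TN = sum(!pred & y == 0))
}

#' Classification metrics for imbalanced presence/absence data
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, informedness (Youden's J), and the Matthews
#' correlation coefficient from a confusion matrix. Any metric with a zero
#' denominator is reported as `NA` with a warning, never silently zero.
#'
#' @param counts named vector with elements `TP`, `FP`, `FN`, `TN` (as from
#'   [confusionCounts()]).
#' @param auc optional AUC to carry through into the report.
#' @param threshold optional threshold to carry through.
#' @return data.frame with one row: `auc, mcc, informedness, accuracy,
#'   sensitivity, specificity, ppv, npv, threshold`.
#' @export
classificationMetrics <- function(counts, auc = NA_real_,
                                  threshold = NA_real_) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  n <- tp + fp + fn + tn
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  rat <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA",
              call. = FALSE)
      NA_real_
    } else num / den
  }
  sens <- rat(tp, tp + fn, "sensitivity")
  spec <- rat(tn, tn + fp, "specificity")
  mccDen <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen == 0) {
    warning("MCC undefined (empty margin); reported as NA", call. = FALSE)
    NA_real_
  } else (tp * tn - fp * fn) / mccDen
  data.frame(
    auc = auc,
    mcc = mcc,
    informedness = sens + spec - 1,
    accuracy = (tp + tn) / n,
    sensitivity = sens,
    specificity = spec,
    ppv = rat(tp, tp + fp, "PPV"),
    npv = rat(tn, tn + fn, "NPV"),
    threshold = threshold
  )
}

#' Recover the integer confusion matrix behind printed summary metrics
#'
#' Scans every integer `(TP, TN)` pair compatible with the class sizes for
#' the one whose accuracy and informedness round to the printed values.
#' Errors if no pair, or more than one pair, matches.
#'
#' @param nPos,nNeg numbers of observed presences and absences.
#' @param accuracy,informedness printed values, matched after rounding to
#'   `digits` decimals.
#' @param digits printed precision (default 3).
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @examples
#' solveConfusion(116, 29, 0.931, 0.759)
#' @export
solveConfusion <- function(nPos, nNeg, accuracy, informedness, digits = 3) {
  grid <- expand.grid(TP = 0:nPos, TN = 0:nNeg)
  acc <- round((grid$TP + grid$TN) / (nPos + nNeg), digits)
  j <- round(grid$TP / nPos + grid$TN / nNeg - 1, digits)
  hit <- which(acc == round(accuracy, digits) &
                 j == round(informedness, digits))
  if (length(hit) == 0) {
    stop("no integer confusion matrix matches accuracy ", accuracy,
         " and informedness ", informedness, call. = FALSE)
  }
  if (length(hit) > 1) {
    stop("ambiguous: ", length(hit), " confusion matrices match: ",
         paste(sprintf("(TP=%d,TN=%d)", grid$TP[hit], grid$TN[hit]),
               collapse = " "), call. = FALSE)
  }
  tp <- grid$TP[hit]; tn <- grid$TN[hit]
  c(TP = tp, FP = nNeg - tn, FN = nPos - tp, TN = tn)
}

#' Screen predictors for collinearity
#'
#' Pairwise Pearson correlations among candidate predictors; pairs at or
#' above the cutoff in absolute value are flagged. Zero-variance columns
#' are reported with `NA` correlation, flagged, and never crash the screen.
#'
#' @param predictors data.frame of numeric predictor columns (>= 2).
#' @param cutoff absolute-correlation flag threshold (default 0.7).
#' @return data.frame with columns `var1`, `var2`, `r`, `flagged`.
#' @export
collinearityScreen <- function(predictors, cutoff = 0.7) {
  x <- as.data.frame(predictors)
  if (ncol(x) < 2) stop("need at least 2 predictors", call. = FALSE)
  sds <- vapply(x, stats::sd, numeric(1))
  pairs <- utils::combn(names(x), 2)
  rows <- apply(pairs, 2, function(p) {
    r <- if (sds[p[1]] == 0 || sds[p[2]] == 0) NA_real_ else
      stats::cor(x[[p[1]]], x[[p[2]]])
    data.frame(var1 = p[1], var2 = p[2], r = r,
               flagged = is.na(r) || abs(r) >= cutoff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
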