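#' Select the discrimination threshold kappa
#'
#' Enumerates all cut points (midpoints between adjacent distinct sorted
#' scores) and returns the one maximizing Youden's J = TPR - FPR for the
#' rule `predicted positive = score > kappa`. Ties in J are broken toward
#' the higher kappa (fewer predicted positives — conservative triage). The
#' result is invariant to replicating the data set.
#'
#' @param scores numeric classifier scores
#' @param labels binary labels (logical or 0/1); both classes required
#' @return the threshold kappa
#' @export
selectThreshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present to place a threshold")
  s <- sort(unique(scores))
  if (length(s) == 1L) return(s)
  cand <- (head(s, -1) + tail(s, -1)) / 2
  nPos <- sum(labels); nNeg <- sum(!labels)
  j <- vapply(cand, function(k)
    sum(labels & scores > k) / nPos - sum(!labels & scores > k) / nNeg,
    numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

#' Distance-to-boundary confidence
#'
#' `(score - kappa) / (scoreMax - kappa)` above the threshold and
#' `(score - kappa) / (scoreMin - kappa)` at or below it, where scoreMin
#' and scoreMax are the training-set score extrema. Scores outside the
#' training extrema are clipped to confidence 1.
#'
#' @param scores numeric score(s)
#' @param kappa discrimination threshold, strictly inside
#'   `(scoreMin, scoreMax)`
#' @param scoreMin,scoreMax training-set score extrema
#' @return confidence value(s) in [0, 1]
#' @export
confidenceValue <- function(scores, kappa, scoreMin, scoreMax) {
  if (!(scoreMin < kappa && kappa < scoreMax))
    stop("kappa must lie strictly between the training score extrema ",
         "(degenerate normalizer otherwise)")
  conf <- ifelse(scores > kappa,
                 (scores - kappa) / (scoreMax - kappa),
                 (scores - kappa) / (scoreMin - kappa))
  pmin(pmax(conf, 0), 1)
}

#' Empirical confidence-percentile thresholds
#'
#' For each percentile p, the threshold t_p such that p% of trials have
#' confidence strictly below t_p: t_p is the `floor(p/100 * n) + 1`-th
#' order statistic, so p = 0 keeps every trial in the high-confidence
#' subset and ties at the boundary all stay retained (`confidence >= t_p`).
#'
#' @param confidences numeric confidences
#' @param percentiles percent values, default 0 to 90 by 10
#' @return named numeric, one threshold per percentile
#' @export
percentileThresholds <- function(confidences, percentiles = seq(0, 90, 10)) {
  if (!length(confidences)) stop("no confidences supplied")
  s <- sort(confidences)
  n <- length(s)
  th <- vapply(percentiles,
               function(p) s[min(floor(p / 100 * n) + 1, n)], numeric(1))
  names(th) <- paste0(percentiles, "%")
  th
}

#' Score, threshold and attach confidences to a trial set
#'
#' Bundles classifier scores with a threshold, the training-set score
#' extrema, confidences and predictions into a [ScoredTrials-class].
#' `kappa` is clipped strictly inside `(scoreMin, scoreMax)` if it falls on
#' or outside an extremum (a validation threshold can exceed the training
#' range).
#'
#' @param scores per-trial scores
#' @param kappa discrimination threshold
#' @param scoreMin,scoreMax training-set score extrema
#' @param trueClass stimulus class per trial
#' @param fold originating fold per trial (default 1)
#' @return a [ScoredTrials-class]
#' @export
scoreTrials <- function(scores, kappa, scoreMin, scoreMax, trueClass,
                        fold = rep(1L, length(scores))) {
  eps <- (scoreMax - scoreMin) * 1e-9
  kappa <- min(max(kappa, scoreMin + eps), scoreMax - eps)
  new("ScoredTrials", scores = scores, kappa = kappa,
      scoreMin = scoreMin, scoreMax = scoreMax,
      confidences = confidenceValue(scores, kappa, scoreMin, scoreMax),
      predicted = scores > kappa, trueClass = trueClass,
      fold = as.integer(fold))
}
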