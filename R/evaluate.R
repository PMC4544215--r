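#' Nested contiguous 10-fold scheme
#'
#' Trials (assumed time-ordered) are cut into `nFolds` contiguous slices of
#' near-equal size (the first `n mod nFolds` slices get the extra trial).
#' In fold k, slice k is the validation set, slice k + 1 (circularly)
#' establishes the discrimination threshold, and the remaining slices
#' (80% for 10 folds) train the spatial filters and classifier; every
#' slice serves as validation exactly once.
#'
#' @param nTrialsTotal number of trials
#' @param nFolds number of folds (default 10)
#' @return a [FoldScheme-class]
#' @export
makeFolds <- function(nTrialsTotal, nFolds = 10L) {
  if (nTrialsTotal < nFolds)
    stop("need at least ", nFolds, " trials for ", nFolds, " folds")
  base <- nTrialsTotal %/% nFolds
  extra <- nTrialsTotal %% nFolds
  sizes <- rep(base, nFolds) + rep(c(1L, 0L), c(extra, nFolds - extra))
  ends <- cumsum(sizes)
  slices <- Map(function(a, b) seq.int(a, b), ends - sizes + 1L, ends)
  new("FoldScheme", slices = slices, nFolds = as.integer(nFolds))
}

#' Fold role assignments
#'
#' @param scheme a [FoldScheme-class]
#' @param fold fold number in 1..nFolds
#' @return list of trial-index vectors `train`, `threshold`, `validation`
#' @export
foldAssignments <- function(scheme, fold) {
  k <- scheme@nFolds
  thr <- fold %% k + 1L
  list(train = unlist(scheme@slices[-c(fold, thr)], use.names = FALSE),
       threshold = scheme@slices[[thr]],
       validation = scheme@slices[[fold]])
}

#' Area under the ROC curve
#'
#' Trapezoidal ROC area, computed as the Mann-Whitney probability that a
#' random positive outscores a random negative, with ties counted half.
#'
#' @param scores numeric scores
#' @param labels binary labels; both classes required
#' @return Az in [0, 1]
#' @export
azScore <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute Az")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class misclassification proportions
#'
#' Targets are misclassified when predicted non-target; non-targets and
#' backgrounds when predicted target. Classes with no trials are omitted
#' with a message.
#'
#' @param predicted logical, predicted target per trial
#' @param trueClass stimulus class per trial
#' @return named numeric proportions
#' @export
misclassificationRates <- function(predicted, trueClass) {
  stopifnot(length(predicted) == length(trueClass))
  out <- numeric()
  for (cls in intersect(STIMULUS_CLASSES, unique(trueClass))) {
    idx <- trueClass == cls
    out[cls] <- if (cls == "target") mean(!predicted[idx])
                else mean(predicted[idx])
  }
  missing <- setdiff(STIMULUS_CLASSES, names(out))
  if (length(missing))
    message("misclassificationRates: no trials of class ",
            paste(missing, collapse = ", "), "; omitted")
  out
}

#' Run the full nested cross-validated classification pipeline
#'
#' For each of three discriminations — target vs background in the TO
#' condition (`to_tvb`), target vs background in the TN condition with
#' non-targets excluded before fold construction (`tn_tvb`), or target vs
#' both non-target and background (`tn_tvbnt`) — runs, per fold: xDAWN
#' filter training on the training slices, BLDA fitting on the filtered
#' training features, threshold selection (on the threshold slice by
#' default, or on the training scores via `thresholdOn = "train"`), and
#' scoring/confidence/prediction on the validation slice using the
#' training-set score extrema. Validation results are pooled across folds
#' in time order.
#'
#' @param epochs classifier-ready [EpochedData-class] (time-ordered,
#'   3-class labels)
#' @param discrimination one of `"to_tvb"`, `"tn_tvb"`, `"tn_tvbnt"`
#' @param nFilters xDAWN filters to keep
#' @param nFolds cross-validation folds
#' @param thresholdOn slice used to establish kappa
#' @param lambda ridge scale for the xDAWN data covariance
#' @return an [EvaluationReport-class]
#' @export
runPipeline <- function(epochs,
                        discrimination = c("to_tvb", "tn_tvb", "tn_tvbnt"),
                        nFilters = 8L, nFolds = 10L,
                        thresholdOn = c("threshold", "train"),
                        lambda = 1e-9) {
  discrimination <- match.arg(discrimination)
  thresholdOn <- match.arg(thresholdOn)
  if (discrimination %in% c("to_tvb", "tn_tvb"))
    epochs <- epochs[labels(epochs) %in% c("target", "background")]
  y <- labels(epochs) == "target"
  n <- nTrials(epochs)
  scheme <- makeFolds(n, nFolds)
  scores <- numeric(n); conf <- numeric(n)
  predicted <- logical(n); foldOf <- integer(n)
  azPerFold <- numeric(nFolds)
  kappas <- numeric(nFolds); mins <- numeric(nFolds); maxs <- numeric(nFolds)
  for (k in seq_len(nFolds)) {
    a <- foldAssignments(scheme, k)
    filters <- xdawnTrain(epochs[a$train], nFilters = nFilters,
                          lambda = lambda)
    featTrain <- applyFilters(epochs[a$train], filters)
    model <- fitBLDA(featTrain, y[a$train])
    scoresTrain <- bldaScore(model, featTrain)
    useTrain <- thresholdOn == "train"
    if (!useTrain && (all(y[a$threshold]) || !any(y[a$threshold]))) {
      message("runPipeline: fold ", k, " threshold slice is single-class; ",
              "falling back to training scores for kappa")
      useTrain <- TRUE
    }
    kappaScores <- if (useTrain) scoresTrain
                   else bldaScore(model, applyFilters(epochs[a$threshold],
                                                      filters))
    kappaLabels <- if (useTrain) y[a$train] else y[a$threshold]
    kappa <- selectThreshold(kappaScores, kappaLabels)
    sMin <- min(scoresTrain); sMax <- max(scoresTrain)
    eps <- (sMax - sMin) * 1e-9
    kappa <- min(max(kappa, sMin + eps), sMax - eps)
    sVal <- bldaScore(model, applyFilters(epochs[a$validation], filters))
    scores[a$validation] <- sVal
    conf[a$validation] <- confidenceValue(sVal, kappa, sMin, sMax)
    predicted[a$validation] <- sVal > kappa
    foldOf[a$validation] <- k
    azPerFold[k] <- if (any(y[a$validation]) && !all(y[a$validation]))
      azScore(sVal, y[a$validation]) else NA_real_
    kappas[k] <- kappa; mins[k] <- sMin; maxs[k] <- sMax
  }
  scored <- new("ScoredTrials", scores = scores,
                kappa = stats::median(kappas),
                scoreMin = min(mins), scoreMax = max(maxs),
                confidences = conf, predicted = predicted,
                trueClass = labels(epochs), fold = foldOf)
  new("EvaluationReport",
      azPooled = azScore(scores, y),
      azPerFold = azPerFold,
      misclass = misclassificationRates(predicted, labels(epochs)),
      scored = scored,
      discrimination = discrimination)
}

#' Confidence-threshold sweep
#'
#' For each confidence percentile p (default 0-90% by 10%), computes the
#' threshold below which p% of trials fall, then on the retained
#' (high-confidence) subset: Az (omitted with a message when only one
#' class remains), per-class misclassification, and retained fractions.
#' Mitigated metrics from [simulateMitigation()] — manual relabeling of
#' every trial below the threshold — are reported alongside, over all
#' trials.
#'
#' @param report an [EvaluationReport-class] or [ScoredTrials-class]
#' @param percentiles percent values
#' @return data.frame, one row per percentile
#' @export
sweepConfidence <- function(report, percentiles = seq(0, 90, 10)) {
  scored <- if (is(report, "EvaluationReport")) report@scored else report
  conf <- scored@confidences
  y <- scored@trueClass == "target"
  th <- percentileThresholds(conf, percentiles)
  rows <- lapply(seq_along(percentiles), function(i) {
    t <- th[i]
    keep <- conf >= t
    az <- if (any(y[keep]) && !all(y[keep])) azScore(scored@scores[keep], y[keep])
          else { message("sweepConfidence: single-class retained subset at ",
                         percentiles[i], "%; Az omitted"); NA_real_ }
    mis <- misclassificationRates(scored@predicted[keep],
                                  scored@trueClass[keep])
    mit <- simulateMitigation(scored, t)
    retByClass <- vapply(STIMULUS_CLASSES, function(cls) {
      idx <- scored@trueClass == cls
      if (any(idx)) mean(keep[idx]) else NA_real_
    }, numeric(1))
    data.frame(percentile = percentiles[i], threshold = unname(t),
               retained_fraction = mean(keep),
               retained_target = retByClass[["target"]],
               retained_nontarget = retByClass[["nontarget"]],
               retained_background = retByClass[["background"]],
               az = az,
               az_mitigated = mit$az,
               misclass_target = mis["target"],
               misclass_nontarget = if ("nontarget" %in% names(mis))
                 mis[["nontarget"]] else NA_real_,
               misclass_background = mis["background"],
               misclass_target_mitigated = mit$misclass["target"],
               misclass_nontarget_mitigated =
                 if ("nontarget" %in% names(mit$misclass))
                   mit$misclass[["nontarget"]] else NA_real_,
               misclass_background_mitigated = mit$misclass["background"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Simulated manual-relabeling mitigation
#'
#' Trials with confidence below the threshold are routed to a manual
#' labeler assumed perfectly accurate, i.e. they receive their true label;
#' metrics are recomputed over *all* trials. For Az, manual trials enter
#' as maximal-certainty scores (above the maximum for true targets, below
#' the minimum otherwise) so they do not perturb the ordering of retained
#' trials.
#'
#' @param scored a [ScoredTrials-class]
#' @param threshold confidence threshold; trials with
#'   `confidence < threshold` are manually labeled
#' @return list with `az`, named `misclass`, and `manual_fraction`
#' @export
simulateMitigation <- function(scored, threshold) {
  y <- scored@trueClass == "target"
  manual <- scored@confidences < threshold
  predicted <- scored@predicted
  predicted[manual] <- y[manual]
  s <- scored@scores
  eps <- (max(s) - min(s)) * 1e-6 + 1e-12
  s[manual & y] <- max(scored@scores) + eps
  s[manual & !y] <- min(scored@scores) - eps
  list(az = azScore(s, y),
       misclass = misclassificationRates(predicted, scored@trueClass),
       manual_fraction = mean(manual))
}

#' Manual-labeling time overhead
#'
#' Percent increase in total labeling time when a fraction of trials is
#' manually labeled: `100 * manualFraction * secondsPerManual /
#' secondsPerImage`, with 1 s per manual label and 0.5 s per RSVP image
#' (the 2 Hz presentation) as defaults — so manually labeling 30% of the
#' data costs 60% extra time.
#'
#' @param manualFraction fraction of trials manually labeled, in [0, 1]
#' @param secondsPerManual seconds to label one image manually
#' @param secondsPerImage seconds each image occupies in the RSVP stream
#' @return percent overhead
#' @export
labelingTimeOverhead <- function(manualFraction, secondsPerManual = 1,
                                 secondsPerImage = 0.5) {
  if (manualFraction < 0 || secondsPerManual < 0)
    stop("inputs must be non-negative")
  if (secondsPerImage <= 0)
    stop("secondsPerImage must be positive")
  100 * manualFraction * secondsPerManual / secondsPerImage
}
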