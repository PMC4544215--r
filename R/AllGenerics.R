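#' Number of trials
#' @param x an object with a trial dimension
#' @return integer trial count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Sampling rate in Hz
#' @param x an object carrying sampling metadata
#' @return numeric sampling rate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel labels
#' @param x an object carrying channel metadata
#' @return character vector of labels
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Underlying numeric data
#' @param x a container object
#' @return the wrapped matrix or array
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' Sample times of an epoch grid, in ms relative to stimulus onset
#' @param x an epoched or averaged object
#' @return numeric vector of per-sample times
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Per-trial classifier scores
#' @param x a [ScoredTrials-class] or [EvaluationReport-class]
#' @return numeric scores
#' @export
setGeneric("trialScores", function(x) standardGeneric("trialScores"))

#' Per-trial confidences
#' @param x a [ScoredTrials-class] or [EvaluationReport-class]
#' @return numeric confidences in [0, 1]
#' @export
setGeneric("trialConfidences", function(x) standardGeneric("trialConfidences"))

#' @describeIn nTrials trials in an epoched array
#' @export
setMethod("nTrials", "EpochedData", function(x) dim(x@data)[1L])

#' @describeIn nTrials per-class trial counts behind the averages
#' @export
setMethod("nTrials", "ERPSet", function(x) x@nTrials)

#' @describeIn nTrials scored validation trials
#' @export
setMethod("nTrials", "ScoredTrials", function(x) length(x@scores))

#' @describeIn samplingRate continuous recording
#' @export
setMethod("samplingRate", "ContinuousEEG", function(x) x@samplingRate)

#' @describeIn samplingRate epoched data
#' @export
setMethod("samplingRate", "EpochedData", function(x) x@samplingRate)

#' @describeIn samplingRate averaged waveforms
#' @export
setMethod("samplingRate", "ERPSet", function(x) x@samplingRate)

#' @describeIn channelLabels continuous recording
#' @export
setMethod("channelLabels", "ContinuousEEG", function(x) x@channelLabels)

#' @describeIn channelLabels epoched data
#' @export
setMethod("channelLabels", "EpochedData", function(x) x@channelLabels)

#' @describeIn channelLabels averaged waveforms
#' @export
setMethod("channelLabels", "ERPSet", function(x) x@channelLabels)

#' @describeIn channelLabels channel order a filter set expects
#' @export
setMethod("channelLabels", "SpatialFilterSet", function(x) x@channelLabels)

#' @describeIn eegData channels x samples matrix
#' @export
setMethod("eegData", "ContinuousEEG", function(x) x@data)

#' @describeIn eegData trials x channels x samples array
#' @export
setMethod("eegData", "EpochedData", function(x) x@data)

sampleGrid <- function(window, rate) {
  start <- ceiling(window[1] * rate / 1000)
  n <- round((window[2] - window[1]) * rate / 1000)
  (start + seq_len(n) - 1) / rate * 1000
}

#' @describeIn epochTimes per-sample times of the epoch grid
#' @export
setMethod("epochTimes", "EpochedData", function(x) sampleGrid(x@window, x@samplingRate))

#' @describeIn epochTimes per-sample times of the average grid
#' @export
setMethod("epochTimes", "ERPSet", function(x) sampleGrid(x@window, x@samplingRate))

#' @describeIn trialScores scores of pooled validation trials
#' @export
setMethod("trialScores", "ScoredTrials", function(x) x@scores)

#' @describeIn trialScores scores inside an evaluation report
#' @export
setMethod("trialScores", "EvaluationReport", function(x) x@scored@scores)

#' @describeIn trialConfidences confidences of pooled validation trials
#' @export
setMethod("trialConfidences", "ScoredTrials", function(x) x@confidences)

#' @describeIn trialConfidences confidences inside an evaluation report
#' @export
setMethod("trialConfidences", "EvaluationReport", function(x) x@scored@confidences)

#' Trial class labels
#' @param object an [EpochedData-class] or [ScoredTrials-class]
#' @param ... unused
#' @return character vector of stimulus classes, one per trial
#' @export
setMethod("labels", "EpochedData", function(object, ...) object@labels)

#' @describeIn labels-EpochedData-method true classes of scored trials
#' @export
setMethod("labels", "ScoredTrials", function(object, ...) object@trueClass)

#' Subset epoched data by trial
#' @param x an [EpochedData-class]
#' @param i trial indices (integer or logical)
#' @param j,...,drop unused
#' @return an [EpochedData-class] with the selected trials
#' @export
setMethod("[", "EpochedData", function(x, i, j, ..., drop = FALSE) {
  new("EpochedData",
      data = x@data[i, , , drop = FALSE],
      samplingRate = x@samplingRate, window = x@window,
      labels = x@labels[i], onsets = x@onsets[i],
      channelLabels = x@channelLabels, pzChannel = x@pzChannel)
})

setMethod("show", "EventSequence", function(object) {
  tab <- table(factor(object@classes, levels = STIMULUS_CLASSES))
  cat("EventSequence:", length(object@onsets), "stimuli in",
      length(unique(object@blockIds)), "block(s)\n")
  cat("  counts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  presses:", length(object@presses), "\n")
})

setMethod("show", "ContinuousEEG", function(object) {
  cat("ContinuousEEG:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@samplingRate, "Hz (",
      round(ncol(object@data) / object@samplingRate, 1), "s )\n")
  cat("  Pz-role channel:", object@pzChannel, "\n")
})

setMethod("show", "EpochedData", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@labels, levels = STIMULUS_CLASSES))
  cat("EpochedData:", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", object@samplingRate, "Hz, window [",
      object@window[1], ",", object@window[2], ") ms\n")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ERPSet", function(object) {
  cat("ERPSet:", paste(names(object@waveforms), collapse = ", "),
      "| n =", paste(object@nTrials, collapse = ", "), "\n")
})

setMethod("show", "SpatialFilterSet", function(object) {
  cat("SpatialFilterSet:", ncol(object@u), "filters over",
      nrow(object@u), "channels\n")
  cat("  SSNR:", paste(signif(object@ssnr, 4), collapse = ", "), "\n")
})

setMethod("show", "BLDAModel", function(object) {
  cat("BLDAModel:", length(object@weights), "features | alpha =",
      signif(object@alpha, 4), "beta =", signif(object@beta, 4),
      "|", object@nIterations, "iterations",
      if (object@converged) "(converged)" else "(not converged)", "\n")
})

setMethod("show", "ScoredTrials", function(object) {
  cat("ScoredTrials:", length(object@scores), "trials | kappa =",
      signif(object@kappa, 4), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@discrimination, ")\n", sep = "")
  cat("  pooled Az:", round(object@azPooled, 4), "| per-fold mean:",
      round(mean(object@azPerFold), 4), "\n")
  cat("  misclassification:",
      paste(names(object@misclass), signif(object@misclass, 3),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BehavioralCounts", function(object) {
  cat("BehavioralCounts: hits =", object@hits, "misses =", object@misses, "\n")
  cat("  FP:", paste(names(object@fp), object@fp, sep = "=", collapse = ", "),
      "| CR:", paste(names(object@cr), object@cr, sep = "=", collapse = ", "), "\n")
})
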