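#' @import methods
#' @importFrom stats median qnorm rnorm runif rlnorm rbinom sd var fft
#' @importFrom utils head tail
NULL

STIMULUS_CLASSES <- c("target", "nontarget", "background")

#' Simulation configuration for a synthetic RSVP session
#'
#' Holds every parameter of the generator: session layout (blocks, duration,
#' presentation rate), stimulus-class ratios and spacing constraints, the
#' evoked-response model (class amplitudes, template shape, spatial pattern),
#' the noise model, and the behavioral response model. Build instances with
#' [simulationConfig()], which fills condition-dependent defaults.
#'
#' @slot condition "TO" (targets among backgrounds) or "TN" (targets plus
#'   rare non-targets among backgrounds).
#' @slot nBlocks number of RSVP blocks.
#' @slot blockDuration block length in seconds.
#' @slot presentationRate stimulus rate in Hz.
#' @slot targetRatio x in the 1:x target:background ratio.
#' @slot nontargetRatio x in the 1:x non-target:background ratio (TN only;
#'   NA for TO).
#' @slot minBackgroundGap minimum number of background stimuli required to
#'   follow every rare (target or non-target) stimulus.
#' @slot nChannels,samplingRate,channelLabels,pzChannel EEG geometry; one
#'   channel plays the midline-parietal ("Pz") role where the evoked
#'   response is maximal.
#' @slot erpAmplitudes named numeric, mean evoked amplitude (uV) over
#'   `erpWindow` at the Pz-role channel for each stimulus class.
#' @slot erpPeakMs,erpHalfWidthMs raised-cosine template peak latency and
#'   half width (ms).
#' @slot erpWindow ms window over which `erpAmplitudes` are defined.
#' @slot noiseModel "pink" or "white".
#' @slot noiseScale noise standard deviation in uV.
#' @slot pressProb named numeric, per-class button-press probability.
#' @slot rtMedianMs,rtLogSd log-normal reaction-time law: median (ms) and
#'   log-scale standard deviation.
#' @slot seed integer seed that fully determines all generator outputs.
#' @export
setClass("SimulationConfig", slots = c(
  condition = "character",
  nBlocks = "integer",
  blockDuration = "numeric",
  presentationRate = "numeric",
  targetRatio = "numeric",
  nontargetRatio = "numeric",
  minBackgroundGap = "integer",
  nChannels = "integer",
  samplingRate = "numeric",
  channelLabels = "character",
  pzChannel = "character",
  erpAmplitudes = "numeric",
  erpPeakMs = "numeric",
  erpHalfWidthMs = "numeric",
  erpWindow = "numeric",
  noiseModel = "character",
  noiseScale = "numeric",
  pressProb = "numeric",
  rtMedianMs = "numeric",
  rtLogSd = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!object@condition %in% c("TO", "TN"))
    msg <- c(msg, "condition must be 'TO' or 'TN'")
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@blockDuration <= 0) msg <- c(msg, "blockDuration must be > 0")
  if (object@presentationRate <= 0) msg <- c(msg, "presentationRate must be > 0")
  if (object@minBackgroundGap < 0L) msg <- c(msg, "minBackgroundGap must be >= 0")
  if (!all(STIMULUS_CLASSES %in% names(object@erpAmplitudes)))
    msg <- c(msg, "erpAmplitudes needs target/nontarget/background entries")
  if (!all(STIMULUS_CLASSES %in% names(object@pressProb)))
    msg <- c(msg, "pressProb needs target/nontarget/background entries")
  if (any(object@pressProb < 0 | object@pressProb > 1))
    msg <- c(msg, "pressProb entries must lie in [0, 1]")
  if (object@rtMedianMs <= 0 || object@rtLogSd <= 0)
    msg <- c(msg, "reaction-time parameters must be positive")
  if (!object@noiseModel %in% c("pink", "white"))
    msg <- c(msg, "noiseModel must be 'pink' or 'white'")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(object@channelLabels) != object@nChannels)
    msg <- c(msg, "channelLabels length must equal nChannels")
  if (!object@pzChannel %in% object@channelLabels)
    msg <- c(msg, "pzChannel must be one of channelLabels")
  if (length(msg)) msg else TRUE
})

#' Ordered stimulus events and button presses of one RSVP session
#'
#' The shared substrate of the simulator and the behavioral analysis:
#' stimulus onsets (seconds from session start), one class label per onset,
#' per-onset block ids, and (possibly empty) sorted button-press times.
#'
#' @slot onsets strictly increasing onset times in seconds.
#' @slot classes one of "target", "nontarget", "background" per onset.
#' @slot blockIds integer block index per onset.
#' @slot presses sorted button-press times in seconds (may be empty).
#' @export
setClass("EventSequence", slots = c(
  onsets = "numeric",
  classes = "character",
  blockIds = "integer",
  presses = "numeric"
))

setValidity("EventSequence", function(object) {
  msg <- character()
  n <- length(object@onsets)
  if (length(object@classes) != n || length(object@blockIds) != n)
    msg <- c(msg, "onsets, classes and blockIds must have equal length")
  if (n > 1 && any(diff(object@onsets) <= 0))
    msg <- c(msg, "onsets must be strictly increasing")
  if (!all(object@classes %in% STIMULUS_CLASSES))
    msg <- c(msg, "classes must be target/nontarget/background")
  if (length(object@presses) > 1 && is.unsorted(object@presses))
    msg <- c(msg, "presses must be sorted")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel EEG
#'
#' A channels x samples matrix in microvolts with sampling metadata and a
#' designated midline-parietal ("Pz"-role) channel.
#'
#' @slot data channels x samples numeric matrix, uV.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels one label per row of `data`.
#' @slot pzChannel label of the Pz-role channel.
#' @export
setClass("ContinuousEEG", slots = c(
  data = "matrix",
  samplingRate = "numeric",
  channelLabels = "character",
  pzChannel = "character"
))

setValidity("ContinuousEEG", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "nrow(data) must equal length(channelLabels)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (!object@pzChannel %in% object@channelLabels)
    msg <- c(msg, "pzChannel must be one of channelLabels")
  if (length(msg)) msg else TRUE
})

#' Epoched single-trial EEG
#'
#' Trials x channels x samples array cut around stimulus onsets. All trials
#' share the epoch window and sampling rate; trial order follows event
#' (time) order. The sample grid uses the half-open convention
#' `[start, end)` with the onset mapped to sample index
#' `ceil(start * rate / 1000)` relative to time zero, so a `[0, 1000)` ms
#' window at 32 Hz yields exactly 32 samples.
#'
#' @slot data trials x channels x samples array, uV.
#' @slot samplingRate Hz.
#' @slot window `c(start, end)` in ms relative to stimulus onset.
#' @slot labels stimulus class per trial.
#' @slot onsets onset time (s) per trial.
#' @slot channelLabels,pzChannel channel metadata.
#' @export
setClass("EpochedData", slots = c(
  data = "array",
  samplingRate = "numeric",
  window = "numeric",
  labels = "character",
  onsets = "numeric",
  channelLabels = "character",
  pzChannel = "character"
))

setValidity("EpochedData", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x samples)")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "one label per trial required")
    if (d[1] != length(object@onsets))
      msg <- c(msg, "one onset per trial required")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "one channel label per channel required")
  }
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing ms pair")
  if (length(msg)) msg else TRUE
})

#' Class-conditional average waveforms
#'
#' @slot waveforms named list (stimulus class -> channels x samples matrix).
#' @slot nTrials named integer, trials averaged per class.
#' @slot window epoch window in ms.
#' @slot samplingRate Hz.
#' @slot channelLabels,pzChannel channel metadata.
#' @export
setClass("ERPSet", slots = c(
  waveforms = "list",
  nTrials = "integer",
  window = "numeric",
  samplingRate = "numeric",
  channelLabels = "character",
  pzChannel = "character"
))

setValidity("ERPSet", function(object) {
  msg <- character()
  if (!length(object@waveforms))
    msg <- c(msg, "at least one class waveform required")
  if (!identical(names(object@waveforms), names(object@nTrials)))
    msg <- c(msg, "waveforms and nTrials must share class names")
  if (any(object@nTrials <= 0L))
    msg <- c(msg, "nTrials must be positive for every included class")
  if (length(msg)) msg else TRUE
})

#' Button-press attribution counts
#'
#' Signal-detection bookkeeping: hits and misses over target stimuli,
#' false positives and correct rejects per non-target class, and the
#' hit reaction times.
#'
#' @slot hits,misses counts over target stimuli.
#' @slot fp named counts of false positives per class
#'   (nontarget, background).
#' @slot cr named counts of correct rejects per class.
#' @slot rts reaction times of hits, in ms.
#' @export
setClass("BehavioralCounts", slots = c(
  hits = "integer",
  misses = "integer",
  fp = "integer",
  cr = "integer",
  rts = "numeric"
))

setValidity("BehavioralCounts", function(object) {
  msg <- character()
  if (object@hits < 0L || object@misses < 0L)
    msg <- c(msg, "hit/miss counts must be non-negative")
  if (!all(c("nontarget", "background") %in% names(object@fp)) ||
      !all(c("nontarget", "background") %in% names(object@cr)))
    msg <- c(msg, "fp and cr need nontarget and background entries")
  if (length(object@rts) != object@hits)
    msg <- c(msg, "one reaction time per hit required")
  if (length(msg)) msg else TRUE
})

#' Toeplitz design matrices of the evoked-response model
#'
#' D1 marks target onsets, D2 marks all stimulus onsets; column k of each is
#' column 1 shifted down by k - 1 samples, so `D %*% A` superimposes an
#' `n x channels` response prototype at every marked onset.
#'
#' @slot d1 samples x n1 sparse 0/1 Toeplitz matrix (target onsets).
#' @slot d2 samples x n2 sparse 0/1 Toeplitz matrix (all onsets).
#' @slot n1,n2 modeled response lengths in samples.
#' @export
setClass("DesignMatrices", slots = c(
  d1 = "Matrix",
  d2 = "Matrix",
  n1 = "integer",
  n2 = "integer"
))

#' xDAWN spatial filter set
#'
#' @slot u channels x nFilters filter weight matrix, columns ordered by
#'   decreasing SSNR and normalized to unit norm in the (regularized)
#'   data-covariance metric.
#' @slot ssnr signal to signal-plus-noise Rayleigh quotient per filter,
#'   descending.
#' @slot a1 n1 x channels least-squares estimate of the target evoked
#'   response.
#' @slot a2 n2 x channels least-squares estimate of the response common to
#'   all stimuli.
#' @slot channelLabels channel order the filters expect.
#' @export
setClass("SpatialFilterSet", slots = c(
  u = "matrix",
  ssnr = "numeric",
  a1 = "matrix",
  a2 = "matrix",
  channelLabels = "character"
))

setValidity("SpatialFilterSet", function(object) {
  msg <- character()
  if (ncol(object@u) != length(object@ssnr))
    msg <- c(msg, "one SSNR value per filter required")
  if (ncol(object@u) > nrow(object@u))
    msg <- c(msg, "cannot have more filters than channels")
  if (is.unsorted(rev(object@ssnr)))
    msg <- c(msg, "ssnr values must be sorted descending")
  if (length(msg)) msg else TRUE
})

#' Bayesian linear discriminant model
#'
#' Linear scoring weights and bias from Bayesian linear regression on
#' class-balanced targets, with isotropic prior precision `alpha` and noise
#' precision `beta` set by evidence maximization.
#'
#' @slot weights per-feature weights.
#' @slot bias scalar intercept.
#' @slot alpha,beta prior and noise precision at the evidence fixed point.
#' @slot nIterations number of update iterations run.
#' @slot converged whether the fixed-point tolerance was reached.
#' @slot evidenceTrace log marginal likelihood after each iteration.
#' @export
setClass("BLDAModel", slots = c(
  weights = "numeric",
  bias = "numeric",
  alpha = "numeric",
  beta = "numeric",
  nIterations = "integer",
  converged = "logical",
  evidenceTrace = "numeric"
))

setValidity("BLDAModel", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@beta <= 0)
    msg <- c(msg, "alpha and beta must be positive")
  if (!all(is.finite(object@weights)) || !is.finite(object@bias))
    msg <- c(msg, "weights and bias must be finite")
  if (length(msg)) msg else TRUE
})

#' Scored validation trials
#'
#' Per-trial classifier scores together with the discrimination threshold
#' kappa, the training-set score extrema used by the confidence measure,
#' the resulting confidences in [0, 1], predicted labels
#' (`score > kappa`), and true stimulus classes.
#'
#' @slot scores classifier score per trial.
#' @slot kappa discrimination threshold.
#' @slot scoreMin,scoreMax training-set score extrema (per-fold values are
#'   applied before pooling; the stored scalars are pooled summaries).
#' @slot confidences per-trial confidence in [0, 1].
#' @slot predicted logical, predicted target per trial.
#' @slot trueClass stimulus class per trial.
#' @slot fold originating cross-validation fold per trial.
#' @export
setClass("ScoredTrials", slots = c(
  scores = "numeric",
  kappa = "numeric",
  scoreMin = "numeric",
  scoreMax = "numeric",
  confidences = "numeric",
  predicted = "logical",
  trueClass = "character",
  fold = "integer"
))

setValidity("ScoredTrials", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (length(object@confidences) != n || length(object@predicted) != n ||
      length(object@trueClass) != n || length(object@fold) != n)
    msg <- c(msg, "per-trial slots must have equal length")
  if (any(object@confidences < 0 | object@confidences > 1, na.rm = TRUE))
    msg <- c(msg, "confidences must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Nested contiguous cross-validation fold scheme
#'
#' Trials are cut into `nFolds` contiguous slices; in fold k, slice k is the
#' validation set, slice k + 1 (circularly) establishes the discrimination
#' threshold, and the remaining slices train the spatial filters and
#' classifier.
#'
#' @slot slices list of contiguous trial-index vectors.
#' @slot nFolds number of folds.
#' @export
setClass("FoldScheme", slots = c(
  slices = "list",
  nFolds = "integer"
))

#' Cross-validated evaluation report
#'
#' @slot azPooled area under the ROC curve over pooled validation scores.
#' @slot azPerFold Az per fold.
#' @slot misclass named per-class misclassification proportions.
#' @slot scored pooled [ScoredTrials-class] in time order.
#' @slot discrimination which discrimination was run.
#' @export
setClass("EvaluationReport", slots = c(
  azPooled = "numeric",
  azPerFold = "numeric",
  misclass = "numeric",
  scored = "ScoredTrials",
  discrimination = "character"
))
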