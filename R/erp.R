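#' Class-conditional grand averages
#'
#' Arithmetic mean over trials for each stimulus class present in the
#' epochs. Classes with no trials are excluded with a message. When press
#' data exist, apply the behavioral filter (hits and correct rejections
#' only) before calling; the average itself is unconditional.
#'
#' @param epochs an [EpochedData-class] (baseline-corrected for ERP use)
#' @param classes classes to include (NULL = all present)
#' @return an [ERPSet-class]
#' @export
grandAverage <- function(epochs, classes = NULL) {
  if (is.null(classes)) classes <- intersect(STIMULUS_CLASSES, epochs@labels)
  waveforms <- list(); n <- integer()
  for (cls in classes) {
    idx <- which(epochs@labels == cls)
    if (!length(idx)) {
      message("grandAverage: class '", cls, "' has no trials; excluded")
      next
    }
    waveforms[[cls]] <- apply(epochs@data[idx, , , drop = FALSE], c(2, 3), mean)
    n[cls] <- length(idx)
  }
  if (!length(waveforms)) stop("no trials in any requested class")
  new("ERPSet", waveforms = waveforms, nTrials = n,
      window = epochs@window, samplingRate = epochs@samplingRate,
      channelLabels = epochs@channelLabels, pzChannel = epochs@pzChannel)
}

#' Windowed mean amplitude per class
#'
#' Mean of the class average waveform at one channel over a half-open ms
#' window (default the 400-800 ms P3 window at the Pz-role channel).
#'
#' @param erps an [ERPSet-class]
#' @param channel channel label; defaults to the Pz-role channel
#' @param window ms pair inside the epoch window
#' @return named numeric, one mean amplitude (uV) per class
#' @export
meanAmplitude <- function(erps, channel = NULL, window = c(400, 800)) {
  if (is.null(channel)) channel <- erps@pzChannel
  ch <- match(channel, erps@channelLabels)
  if (is.na(ch)) stop("unknown channel '", channel, "'")
  if (window[1] < erps@window[1] || window[2] > erps@window[2])
    stop("amplitude window must lie within the epoch window")
  t <- epochTimes(erps)
  idx <- which(t >= window[1] & t < window[2])
  if (!length(idx)) stop("amplitude window contains no samples")
  vapply(erps@waveforms, function(w) mean(w[ch, idx]), numeric(1))
}

#' Difference wave between two classes
#'
#' Pointwise subtraction of class average waveforms (e.g. target minus
#' background).
#'
#' @param erps an [ERPSet-class]
#' @param minuend,subtrahend class names present in `erps`
#' @return channels x samples matrix, uV
#' @export
differenceWave <- function(erps, minuend, subtrahend) {
  for (cls in c(minuend, subtrahend))
    if (!cls %in% names(erps@waveforms))
      stop("class '", cls, "' not present in the ERP set")
  erps@waveforms[[minuend]] - erps@waveforms[[subtrahend]]
}

#' Split trials by confidence and average each side
#'
#' Sorts trials by (confidence, trial index) — the stable tie rule — and
#' averages the top and bottom fractions, per class by default (25% of each
#' class, as in per-class high/low-confidence ERP comparisons) or pooled
#' across classes. The bottom split takes `floor(bottomFrac * n)` trials
#' and the top split `ceiling(topFrac * n)`, so complementary fractions
#' partition all trials. Classes whose split would hold no trial are
#' excluded with a message.
#'
#' @param epochs an [EpochedData-class]
#' @param confidences one confidence per trial
#' @param topFrac,bottomFrac fractions in (0, 1]
#' @param perClass split within each class (TRUE) or over all trials pooled
#' @return list with [ERPSet-class] elements `top` and `bottom`
#' @export
confidenceSplitERPs <- function(epochs, confidences, topFrac = 0.25,
                                bottomFrac = 0.25, perClass = TRUE) {
  if (length(confidences) != nTrials(epochs))
    stop("need one confidence per trial")
  groups <- if (perClass) split(seq_len(nTrials(epochs)), epochs@labels)
            else list(all = seq_len(nTrials(epochs)))
  topIdx <- integer(); bottomIdx <- integer()
  for (g in names(groups)) {
    idx <- groups[[g]]
    ord <- idx[order(confidences[idx], idx)]   # stable: ties by trial index
    nBottom <- floor(bottomFrac * length(ord))
    nTop <- ceiling(topFrac * length(ord))
    if (nBottom < 1 || nTop < 1) {
      message("confidenceSplitERPs: group '", g,
              "' too small for the requested fractions; excluded")
      next
    }
    bottomIdx <- c(bottomIdx, head(ord, nBottom))
    topIdx <- c(topIdx, tail(ord, nTop))
  }
  if (!length(topIdx) || !length(bottomIdx))
    stop("no group large enough for the requested fractions")
  list(top = grandAverage(epochs[sort(topIdx)]),
       bottom = grandAverage(epochs[sort(bottomIdx)]))
}
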