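#' Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass (default 1-10.66 Hz, the
#' classification-stream setting) to every channel. Zero-phase
#' forward-backward application is the default so evoked-response latencies
#' are preserved; set `zeroPhase = FALSE` for causal filtering. DC is
#' removed (the band-pass has zero gain at 0 Hz).
#'
#' @param x a [ContinuousEEG-class]
#' @param low,high cutoff frequencies in Hz; must satisfy
#'   0 < low < high < Nyquist
#' @param order Butterworth prototype order (the digital band-pass has
#'   2 x order poles)
#' @param zeroPhase forward-backward application (doubles the effective
#'   attenuation)
#' @return the filtered [ContinuousEEG-class]
#' @export
bandpassFilter <- function(x, low = 1, high = 10.66, order = 4L,
                           zeroPhase = TRUE) {
  nyq <- x@samplingRate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("cutoffs must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- x@data
  for (c in seq_len(nrow(out))) {
    out[c, ] <- if (zeroPhase) signal::filtfilt(bf, x@data[c, ])
                else signal::filter(bf, x@data[c, ])
  }
  x@data <- out
  x
}

#' Downsample by integer decimation
#'
#' Keeps every k-th sample where k = current rate / target rate. Assumes the
#' signal is already band-limited below the new Nyquist frequency (the
#' 1-10.66 Hz band-pass anti-aliases for the standard 512 -> 32 Hz step).
#'
#' @param x a [ContinuousEEG-class]
#' @param targetRate new sampling rate in Hz; must divide the current rate
#' @return the decimated [ContinuousEEG-class]
#' @export
downsample <- function(x, targetRate) {
  if (targetRate > x@samplingRate)
    stop("targetRate (", targetRate, ") exceeds current rate (",
         x@samplingRate, ")")
  factor <- x@samplingRate / targetRate
  if (abs(factor - round(factor)) > 1e-9)
    stop("targetRate must divide the current sampling rate (factor ",
         signif(factor, 4), " is not an integer)")
  keep <- seq(1, ncol(x@data), by = round(factor))
  x@data <- x@data[, keep, drop = FALSE]
  x@samplingRate <- targetRate
  x
}

#' Cut stimulus-locked epochs from continuous EEG
#'
#' One trial per selected onset, time-ordered and label-preserving. Samples
#' follow the half-open convention `[start, end)`: the onset time maps to
#' the sample `floor(onset * rate) + 1` and the epoch covers sample offsets
#' `ceil(start * rate / 1000)` to that plus
#' `round((end - start) * rate / 1000) - 1`, so a `[0, 1000)` ms window at
#' 32 Hz yields exactly 32 samples. Onsets whose window extends beyond the
#' recording are dropped with a message, never padded.
#'
#' @param x a [ContinuousEEG-class]
#' @param seq the [EventSequence-class] providing onsets and labels
#' @param window `c(start, end)` in ms relative to onset
#' @param classes stimulus classes to keep (NULL = all)
#' @return an [EpochedData-class]
#' @export
epochData <- function(x, seq, window = c(0, 1000), classes = NULL) {
  keep <- if (is.null(classes)) rep(TRUE, length(seq@onsets))
          else seq@classes %in% classes
  if (!any(keep))
    stop("no events of the requested classes")
  onsets <- seq@onsets[keep]
  lab <- seq@classes[keep]
  rate <- x@samplingRate
  startOff <- ceiling(window[1] * rate / 1000)
  nSamp <- round((window[2] - window[1]) * rate / 1000)
  s0 <- floor(onsets * rate) + 1
  first <- s0 + startOff
  last <- first + nSamp - 1
  ok <- first >= 1 & last <= ncol(x@data)
  if (any(!ok))
    message("epochData: dropped ", sum(!ok),
            " trial(s) whose window falls outside the recording")
  if (!any(ok))
    stop("all requested trials fall outside the recording")
  idx <- which(ok)
  out <- array(0, c(length(idx), nrow(x@data), nSamp))
  for (k in seq_along(idx)) {
    i <- idx[k]
    out[k, , ] <- x@data[, first[i]:last[i]]
  }
  new("EpochedData", data = out, samplingRate = rate, window = window,
      labels = lab[idx], onsets = onsets[idx],
      channelLabels = x@channelLabels, pzChannel = x@pzChannel)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline samples
#' (half-open ms window, default `[-500, 0)`), so the baseline mean of the
#' result is zero.
#'
#' @param epochs an [EpochedData-class]
#' @param baseline `c(start, end)` in ms; must lie within the epoch window
#' @return the corrected [EpochedData-class]
#' @export
baselineCorrect <- function(epochs, baseline = c(-500, 0)) {
  if (baseline[1] < epochs@window[1] || baseline[2] > epochs@window[2])
    stop("baseline window must lie within the epoch window")
  t <- epochTimes(epochs)
  idx <- which(t >= baseline[1] & t < baseline[2])
  if (!length(idx))
    stop("baseline window contains no samples")
  bl <- apply(epochs@data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs@data <- epochs@data - array(bl, dim(epochs@data))
  epochs
}

#' Standard classification-stream preprocessing
#'
#' Band-pass (1-10.66 Hz, order 4, zero phase) then decimation to 32 Hz
#' then `[0, 1000)` ms epoching: the fixed order used throughout the
#' single-trial pipeline.
#'
#' @param x a [ContinuousEEG-class]
#' @param seq the [EventSequence-class]
#' @param low,high,order band-pass settings
#' @param targetRate decimation target in Hz
#' @param window epoch window in ms
#' @param classes stimulus classes to keep (NULL = all)
#' @return an [EpochedData-class] ready for [runPipeline()]
#' @export
preprocessForClassification <- function(x, seq, low = 1, high = 10.66,
                                        order = 4L, targetRate = 32,
                                        window = c(0, 1000),
                                        classes = NULL) {
  epochData(downsample(bandpassFilter(x, low, high, order), targetRate),
            seq, window, classes)
}
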