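# Small fast configurations used across the suite. Full-scale study
# conditions appear only in the acceptance tests.

tinyConfig <- function(condition = "TO", seed = 1L, ...) {
  defaults <- list(condition = condition, nBlocks = 1L, blockDuration = 30,
                   nChannels = 4L, samplingRate = 64,
                   channelLabels = c("Fz", "Cz", "Pz", "Oz"), seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

quietly <- function(expr) suppressMessages(expr)

# Epochs built directly from a numeric array, bypassing the generator.
epochsFromArray <- function(arr, rate = 32, window = c(0, 1000),
                            labelsIn = NULL, channels = NULL) {
  d <- dim(arr)
  if (is.null(labelsIn)) labelsIn <- rep("target", d[1])
  if (is.null(channels)) channels <- paste0("C", seq_len(d[2]))
  new("EpochedData", data = arr, samplingRate = rate, window = window,
      labels = labelsIn, onsets = seq_len(d[1]) * 2,
      channelLabels = channels, pzChannel = channels[1])
}

# Brute-force pair-counting AUC oracle (ties count half).
pairCountAz <- function(scores, y) {
  y <- as.logical(y)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive cut-point enumeration oracle for the Youden threshold.
enumThreshold <- function(scores, y) {
  y <- as.logical(y)
  s <- sort(unique(scores))
  cand <- (head(s, -1) + tail(s, -1)) / 2
  j <- sapply(cand, function(k)
    mean(scores[y] > k) - mean(scores[!y] > k))
  best <- which(j >= max(j) - 1e-12)
  list(kappa = cand[max(best)], j = max(j))
}
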