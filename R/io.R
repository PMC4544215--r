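#' Write an event sequence as tab-delimited text
#'
#' Columns `onset_s`, `class`, `block`; button presses are appended as rows
#' with class `"press"` and an empty block field.
#'
#' @param seq an [EventSequence-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEvents <- function(seq, path) {
  df <- data.frame(onset_s = c(seq@onsets, seq@presses),
                   class = c(seq@classes, rep("press", length(seq@presses))),
                   block = c(seq@blockIds, rep(NA, length(seq@presses))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event sequence written by [writeEvents()]
#'
#' @param path tab-delimited events file
#' @return an [EventSequence-class]
#' @export
readEvents <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  isPress <- df$class == "press"
  new("EventSequence",
      onsets = df$onset_s[!isPress],
      classes = df$class[!isPress],
      blockIds = as.integer(df$block[!isPress]),
      presses = sort(df$onset_s[isPress]))
}

#' Write continuous EEG as text plus a JSON sidecar
#'
#' The samples x channels matrix goes to `<path>.tsv` (one column per
#' channel, header = channel labels) and the metadata (sampling rate,
#' channel labels, Pz-role channel) to `<path>.json`.
#'
#' @param x a [ContinuousEEG-class]
#' @param path base path without extension
#' @return `path`, invisibly
#' @export
writeContinuousEEG <- function(x, path) {
  m <- t(x@data)
  colnames(m) <- x@channelLabels
  utils::write.table(m, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = x@samplingRate,
         channel_labels = x@channelLabels,
         pz_channel = x@pzChannel,
         n_samples = ncol(x@data),
         units = "uV"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read continuous EEG written by [writeContinuousEEG()]
#'
#' @param path base path without extension
#' @return a [ContinuousEEG-class]
#' @export
readContinuousEEG <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.delim(paste0(path, ".tsv"), check.names = FALSE))
  new("ContinuousEEG", data = t(m), samplingRate = meta$sampling_rate_hz,
      channelLabels = meta$channel_labels, pzChannel = meta$pz_channel)
}
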