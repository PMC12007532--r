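# The hb_recording container: multi-channel HbO/HbR time series at a
# fixed rate with hemisphere labels and one designated feedback channel.

#' Multi-channel HbO/HbR recording
#'
#' @param hbo,hbr Numeric matrices (samples x channels) of oxy- and
#'   deoxyhaemoglobin series in device concentration units.
#' @param sample_rate Sampling rate in Hz.
#' @param channels Character vector of channel ids (column order).
#' @param hemisphere Character vector (`"left"`/`"right"`) per channel.
#' @param feedback_channel Id of the single feedback channel.
#' @return An object of class `hb_recording`.
#' @export
hb_recording <- function(hbo, hbr, sample_rate = 10,
                         channels = colnames(hbo),
                         hemisphere = NULL,
                         feedback_channel = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr)))
    stop("`hbo` and `hbr` must have identical dimensions")
  if (is.null(channels)) channels <- sprintf("C%02d", seq_len(ncol(hbo)))
  if (length(channels) != ncol(hbo))
    stop("`channels` must name every column")
  if (is.null(hemisphere)) hemisphere <- rep(NA_character_, length(channels))
  if (length(hemisphere) != length(channels))
    stop("`hemisphere` must label every channel")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  if (!is.null(feedback_channel)) {
    if (length(feedback_channel) != 1 || !feedback_channel %in% channels)
      stop("`feedback_channel` must name exactly one existing channel")
  }
  colnames(hbo) <- colnames(hbr) <- channels
  structure(list(
    sample_rate = sample_rate,
    channels = data.frame(channel = channels, hemisphere = hemisphere,
                          stringsAsFactors = FALSE),
    feedback_channel = feedback_channel,
    hbo = hbo, hbr = hbr
  ), class = "hb_recording")
}

#' @export
print.hb_recording <- function(x, ...) {
  cat("<hb_recording> ", ncol(x$hbo), " channels x ", nrow(x$hbo),
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  if (!is.null(x$feedback_channel))
    cat("  feedback channel: ", x$feedback_channel, "\n", sep = "")
  hs <- table(x$channels$hemisphere, useNA = "ifany")
  cat("  hemispheres: ", paste(names(hs), hs, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of samples in a recording
#' @param recording An `hb_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$hbo)

#' Time axis of a recording
#' @param recording An `hb_recording`.
#' @return Sample times in seconds from recording start (0-based).
#' @export
recording_time <- function(recording) {
  (seq_len(n_samples(recording)) - 1) / recording$sample_rate
}

# index of the feedback channel column
fb_index <- function(recording) {
  if (is.null(recording$feedback_channel))
    stop("recording has no designated feedback channel")
  match(recording$feedback_channel, recording$channels$channel)
}
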