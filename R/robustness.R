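# Robustness re-analyses of the feedback signal: a stringent
# 0.01-0.09 Hz band-pass that removes most systemic physiology
# (cardiac ~1 Hz, respiration ~0.3 Hz, Mayer waves ~0.1 Hz), and a
# common average reference over the contralateral hemisphere.

# zero-phase 3rd-order Butterworth band-pass, as a cascade of a
# high-pass and a low-pass section (numerically safer than a single
# narrow band-pass at these corner frequencies)
.bandpass_series <- function(x, sample_rate, low = 0.01, high = 0.09) {
  hp <- signal::butter(3, low / (sample_rate / 2), type = "high")
  lp <- signal::butter(3, high / (sample_rate / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Stringent 0.01-0.09 Hz band-pass
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth band-pass with
#' edges at 0.01 and 0.09 Hz, applied per channel and chromophore.
#' Removes cardiac (~1 Hz), respiratory (~0.3 Hz) and Mayer-wave
#' (~0.1 Hz) components while preserving the task band.
#'
#' @param x An [hb_recording()] or a numeric series.
#' @param sample_rate Sampling rate in Hz (taken from the recording
#'   when `x` is one).
#' @return Filtered object of the same type.
#' @export
bandpass_001_009 <- function(x, sample_rate = 10) {
  if (inherits(x, "hb_recording")) {
    fs <- x$sample_rate
    if (n_samples(x) < 6 * 3 * 3)  # filtfilt needs > 3 * filter order
      stop("series too short for zero-phase filtering")
    x$hbo <- apply(x$hbo, 2, .bandpass_series, sample_rate = fs)
    x$hbr <- apply(x$hbr, 2, .bandpass_series, sample_rate = fs)
    return(x)
  }
  if (length(x) < 6 * 3 * 3)
    stop("series too short for zero-phase filtering")
  .bandpass_series(x, sample_rate)
}

#' Common average reference over the left hemisphere
#'
#' Subtracts the sample-wise mean of all left-hemisphere channels from
#' the (right-hemisphere) feedback channel, per chromophore. Removes
#' global systemic components shared across the montage.
#'
#' @param recording An [hb_recording()] with hemisphere labels and a
#'   right-hemisphere feedback channel.
#' @return A list with the corrected feedback-channel series `hbo` and
#'   `hbr`.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "hb_recording"))
  hemi <- recording$channels$hemisphere
  if (any(is.na(hemi))) stop("hemisphere labels are missing")
  left <- which(hemi == "left")
  if (length(left) == 0) stop("no left-hemisphere channels")
  j <- fb_index(recording)
  if (hemi[j] != "right")
    stop("feedback channel must be on the right hemisphere")
  list(hbo = recording$hbo[, j] - rowMeans(recording$hbo[, left, drop = FALSE]),
       hbr = recording$hbr[, j] - rowMeans(recording$hbr[, left, drop = FALSE]))
}

#' Offline re-analysis of a neurofeedback session
#'
#' Recomputes the per-trial median and standard deviation of the
#' feedback signal offline, replaying the online chain (device filter,
#' per-trial CBSI, 5 s-baseline normalisation, 1 s smoothing) with a
#' variant-specific step inserted before CBSI:
#' \describe{
#'   \item{replication}{the online chain unchanged,}
#'   \item{robust1}{plus the stringent 0.01-0.09 Hz band-pass,}
#'   \item{robust2}{plus the common average reference over the left
#'     hemisphere.}
#' }
#'
#' @param recording Raw [hb_recording()] spanning the schedule.
#' @param schedule An [build_schedule()] event schedule.
#' @param variant `"replication"`, `"robust1"` or `"robust2"`.
#' @param md Baseline centring statistic.
#' @param filters `"causal"` replays the online device filters exactly;
#'   `"zero_phase"` substitutes their forward-backward versions.
#' @return A data frame (one row per regulation trial) with `run`,
#'   `day`, `trial`, `median`, `sd`, and the `variant` as an attribute.
#' @export
offline_reanalysis <- function(recording, schedule,
                               variant = c("replication", "robust1", "robust2"),
                               md = c("median", "mean"),
                               filters = c("causal", "zero_phase")) {
  variant <- match.arg(variant)
  md <- match.arg(md)
  filters <- match.arg(filters)
  validate_schedule(schedule)
  stopifnot(inherits(recording, "hb_recording"))
  fs <- recording$sample_rate

  filtered <- if (filters == "causal") device_preprocess(recording)
              else zero_phase_device_preprocess(recording)
  if (variant == "robust1") filtered <- bandpass_001_009(filtered)
  if (variant == "robust2") {
    car <- common_average_reference(filtered)
    hbo <- car$hbo; hbr <- car$hbr
  } else {
    j <- fb_index(filtered)
    hbo <- filtered$hbo[, j]; hbr <- filtered$hbr[, j]
  }
  sigs <- trial_feedback_signals(hbo, hbr, schedule, fs, md = md)
  out <- do.call(rbind, lapply(sigs, function(s)
    data.frame(run = s$run, day = s$day, trial = s$trial,
               median = stats::median(s$signal),
               sd = stats::sd(s$signal))))
  attr(out, "variant") <- variant
  out
}

#' Zero-phase variant of the device filter chain
#'
#' Forward-backward versions of the device's 0.01 Hz high-pass and
#' 1 Hz low-pass, followed by the same 5 s moving average (centred,
#' two-sided). Used by offline re-analyses when phase distortion must
#' be avoided.
#'
#' @param recording An [hb_recording()].
#' @return The filtered recording.
#' @export
zero_phase_device_preprocess <- function(recording) {
  stopifnot(inherits(recording, "hb_recording"))
  fs <- recording$sample_rate
  hp <- signal::butter(2, 0.01 / (fs / 2), type = "high")
  lp <- signal::butter(2, 1 / (fs / 2), type = "low")
  w <- round(5 * fs)
  if (w %% 2 == 0) w <- w + 1  # centred window
  fil <- function(x) {
    y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
    ma <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    ma[is.na(ma)] <- y[is.na(ma)]
    ma
  }
  recording$hbo <- apply(recording$hbo, 2, fil)
  recording$hbr <- apply(recording$hbr, 2, fil)
  recording
}
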