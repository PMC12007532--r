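# Synthetic fNIRS generator. Emulates a block-design feedback-channel
# response (regulation boxcar convolved with the double-gamma HRF,
# scaled by a per-run regulation amplitude), anticorrelated HbR,
# shared systemic physiology (cardiac ~1 Hz, respiration ~0.3 Hz,
# Mayer waves ~0.1 Hz), slow drift, white noise, a device-export DC
# level, and injected artifacts (spikes, flat lines, high variance).

#' Simulation scenario for a synthetic neurofeedback recording
#'
#' Defines the ground truth of one simulated participant. The default
#' regulation-amplitude trajectories encode the two canonical training
#' outcomes: upregulation sustains a constant positive response across
#' all 12 runs, downregulation starts positive and declines linearly to
#' a negative response by the final runs.
#'
#' @param direction `"up"` or `"down"`; selects the default amplitude
#'   trajectory.
#' @param n_runs Number of scheduled runs (12 for a full training).
#' @param regulation_amplitudes Per-run true response amplitudes in
#'   feedback-signal units; length must equal `n_runs`. Defaults per
#'   `direction`: `rep(1, n_runs)` (up) or a linear decline from 1 to
#'   -1 (down).
#' @param physio_amplitudes Named amplitudes of the shared systemic
#'   components `cardiac` (~1 Hz), `respiration` (~0.3 Hz) and `mayer`
#'   (~0.1 Hz) in signal units.
#' @param physio_freqs Frequencies of those components in Hz. The
#'   cardiac default is 1.1 Hz (66 bpm, a typical resting heart rate).
#' @param drift_slope Slow linear drift in signal units per minute.
#' @param noise_sd White-noise standard deviation per channel.
#' @param hbr_ratio Positive scalar r with neural HbR = -r * neural HbO.
#' @param dc_offset Device-export DC level added to every channel (the
#'   level against which coefficient-of-variation screening operates).
#' @param n_channels Total channel count (split evenly left/right; the
#'   standard bitemporal montage is 2 x 22 = 44).
#' @param feedback_channel Channel id carrying the neural response;
#'   defaults to a right-hemisphere channel.
#' @param artifacts List of artifact specs, each a list with elements
#'   `channel` (id or `"all"`), `kind` (`"spike"`, `"flatline"`,
#'   `"high_variance"`), `onset` and `duration` (seconds), `magnitude`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(direction = c("up", "down"),
                         n_runs = 12L,
                         regulation_amplitudes = NULL,
                         physio_amplitudes = c(cardiac = 0.2,
                                               respiration = 0.3,
                                               mayer = 0.5),
                         physio_freqs = c(cardiac = 1.1,
                                          respiration = 0.3,
                                          mayer = 0.1),
                         drift_slope = 0.1,
                         noise_sd = 0.1,
                         hbr_ratio = 0.5,
                         dc_offset = 10,
                         n_channels = 44L,
                         feedback_channel = NULL,
                         artifacts = list(),
                         seed = NULL) {
  direction <- match.arg(direction)
  if (is.null(regulation_amplitudes)) {
    regulation_amplitudes <- if (direction == "up") rep(1, n_runs)
                             else seq(1, -1, length.out = n_runs)
  }
  if (length(regulation_amplitudes) != n_runs)
    stop("`regulation_amplitudes` must have one entry per run (", n_runs, ")")
  if (hbr_ratio <= 0) stop("`hbr_ratio` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  n_channels <- as.integer(n_channels)
  if (n_channels < 2) stop("need at least 2 channels (one per hemisphere)")
  structure(list(
    direction = direction, n_runs = as.integer(n_runs),
    regulation_amplitudes = regulation_amplitudes,
    physio_amplitudes = physio_amplitudes, physio_freqs = physio_freqs,
    drift_slope = drift_slope, noise_sd = noise_sd,
    hbr_ratio = hbr_ratio, dc_offset = dc_offset,
    n_channels = n_channels, feedback_channel = feedback_channel,
    artifacts = artifacts, seed = seed
  ), class = "sim_scenario")
}

# channel ids and hemisphere labels for an n-channel montage
montage_channels <- function(n_channels) {
  n_left <- n_channels %/% 2L
  n_right <- n_channels - n_left
  data.frame(
    channel = c(sprintf("L%02d", seq_len(n_left)),
                sprintf("R%02d", seq_len(n_right))),
    hemisphere = c(rep("left", n_left), rep("right", n_right)),
    stringsAsFactors = FALSE
  )
}

# regulation boxcar convolved with the HRF, normalised so that a 30 s
# block peaks at 1 (one unit of regulation amplitude = one signal unit
# at the plateau of the response)
.boxcar_cache <- new.env(parent = emptyenv())

# raw convolution of a `dur_samples` boxcar with the HRF kernel,
# including the post-block tail
.block_conv <- function(dur_samples, sample_rate) {
  dt <- 1 / sample_rate
  kern <- hrf(seq(0, 32, by = dt))
  p <- length(kern)
  x <- c(rep(1, dur_samples), numeric(p))
  y <- as.numeric(stats::filter(c(numeric(p - 1), x), kern,
                                method = "convolution", sides = 1)) * dt
  y[p:(p - 1 + length(x))]
}

# single-block response curve, normalised so a unit-amplitude 30 s
# block peaks at 1; cached per (sample_rate, duration)
.block_response <- function(dur_samples, sample_rate) {
  key <- paste(sample_rate, dur_samples)
  if (is.null(.boxcar_cache[[key]])) {
    skey <- paste("scale", sample_rate)
    if (is.null(.boxcar_cache[[skey]]))
      .boxcar_cache[[skey]] <- max(.block_conv(round(30 * sample_rate),
                                               sample_rate))
    .boxcar_cache[[key]] <- .block_conv(dur_samples, sample_rate) /
      .boxcar_cache[[skey]]
  }
  .boxcar_cache[[key]]
}

#' Simulate a multi-channel neurofeedback recording with ground truth
#'
#' Builds an [hb_recording()] that spans `schedule`: the feedback
#' channel carries each regulation block's boxcar convolved with the
#' double-gamma HRF and scaled by that run's true amplitude; every
#' channel shares the scenario's systemic physiology and drift and gets
#' independent white noise; neural HbR is exactly `-hbr_ratio` times
#' neural HbO (correlation -1 by construction) plus independent noise;
#' artifacts are injected per the scenario's spec. The clean neural HbO
#' of every channel is returned alongside as ground truth.
#'
#' @param schedule An [build_schedule()] event schedule.
#' @param scenario A [sim_scenario()]. Its `regulation_amplitudes` must
#'   have exactly one entry per scheduled run.
#' @return A list with elements `recording` (`hb_recording`), `truth`
#'   (clean neural HbO matrix, samples x channels) and `scenario`.
#' @examples
#' sched <- build_schedule(session_config(), seed = 1)
#' sim <- simulate_recording(sched, sim_scenario("up", seed = 1,
#'                                               n_channels = 4))
#' sim$recording
#' @export
simulate_recording <- function(schedule, scenario = sim_scenario()) {
  validate_schedule(schedule)
  stopifnot(inherits(scenario, "sim_scenario"))
  fs <- attr(schedule, "sample_rate")
  if (is.null(fs)) fs <- 10
  n_runs <- max(schedule$run)
  if (length(scenario$regulation_amplitudes) != n_runs)
    stop("scenario has ", length(scenario$regulation_amplitudes),
         " regulation amplitudes for ", n_runs, " scheduled runs")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  total <- max(schedule$onset + schedule$duration)
  n <- ceiling(total * fs)
  t <- (seq_len(n) - 1) / fs
  mon <- montage_channels(scenario$n_channels)
  nch <- nrow(mon)
  fb <- scenario$feedback_channel
  if (is.null(fb)) {
    right <- mon$channel[mon$hemisphere == "right"]
    fb <- right[ceiling(length(right) / 2)]
  }
  fbi <- match(fb, mon$channel)
  if (is.na(fbi)) stop("feedback channel ", fb, " not in montage")

  # neural response on the feedback channel: regulation blocks are
  # disjoint, so the boxcar (x) HRF convolution is the sum of shifted
  # single-block response curves scaled by each run's amplitude
  neural_fb <- numeric(n)
  reg <- schedule[schedule$condition == "regulation", ]
  for (i in seq_len(nrow(reg))) {
    i0 <- floor(reg$onset[i] * fs) + 1
    resp <- .block_response(round(reg$duration[i] * fs), fs)
    i1 <- min(n, i0 + length(resp) - 1)
    idx <- i0:i1
    neural_fb[idx] <- neural_fb[idx] +
      scenario$regulation_amplitudes[reg$run[i]] * resp[seq_along(idx)]
  }
  truth <- matrix(0, n, nch, dimnames = list(NULL, mon$channel))
  truth[, fbi] <- neural_fb

  # shared systemic physiology with randomised phases
  freqs <- scenario$physio_freqs
  physio <- numeric(n)
  for (nm in names(scenario$physio_amplitudes)) {
    a <- scenario$physio_amplitudes[[nm]]
    f <- freqs[[nm]]
    if (is.null(f)) stop("unknown physiological component: ", nm)
    if (a != 0) physio <- physio + a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  drift <- scenario$drift_slope * t / 60

  common <- physio + drift + scenario$dc_offset
  hbo <- truth + common +
    matrix(stats::rnorm(n * nch, sd = scenario$noise_sd), n, nch)
  hbr <- -scenario$hbr_ratio * truth + scenario$dc_offset +
    matrix(stats::rnorm(n * nch, sd = scenario$noise_sd), n, nch)
  colnames(hbo) <- colnames(hbr) <- mon$channel

  # artifact injection
  for (a in scenario$artifacts) {
    chs <- if (identical(a$channel, "all")) mon$channel else a$channel
    i0 <- floor(a$onset * fs) + 1
    i1 <- min(n, floor((a$onset + a$duration) * fs))
    if (i0 > n || i1 < i0) stop("artifact window outside the recording")
    idx <- i0:i1
    for (ch in chs) {
      j <- match(ch, mon$channel)
      if (is.na(j)) stop("artifact channel ", ch, " not in montage")
      if (a$kind == "spike") {
        # triangular motion spike peaking at `magnitude`, positively
        # correlated in HbO and HbR
        tri <- 1 - abs(seq(-1, 1, length.out = length(idx)))
        pulse <- if (max(tri) > 0) a$magnitude * tri / max(tri)
                 else rep(a$magnitude, length(idx))
        hbo[idx, j] <- hbo[idx, j] + pulse
        hbr[idx, j] <- hbr[idx, j] + pulse
      } else if (a$kind == "flatline") {
        hbo[idx, j] <- hbo[i0, j]
        hbr[idx, j] <- hbr[i0, j]
      } else if (a$kind == "high_variance") {
        hbo[idx, j] <- hbo[idx, j] + stats::rnorm(length(idx), sd = a$magnitude)
        hbr[idx, j] <- hbr[idx, j] + stats::rnorm(length(idx), sd = a$magnitude)
      } else stop("unknown artifact kind: ", a$kind)
    }
  }

  rec <- hb_recording(hbo, hbr, sample_rate = fs,
                      channels = mon$channel, hemisphere = mon$hemisphere,
                      feedback_channel = fb)
  list(recording = rec, truth = truth, scenario = scenario)
}
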