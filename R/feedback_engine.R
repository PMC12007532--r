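# The online processing chain: causal device filtering, per-trial CBSI
# motion correction, baseline normalisation, 1 s display smoothing,
# mapping onto the 0-10 feedback scale with direction flip, reward
# accrual, and between-run threshold (k) adaptation.

#' Causal device preprocessing
#'
#' Reproduces the acquisition device's real-time filter chain per
#' channel and chromophore: a causal 2nd-order Butterworth high-pass at
#' 0.01 Hz, a causal 2nd-order Butterworth low-pass at 1 Hz, then a
#' causal 5 s moving average. The high-pass input is referenced to the
#' first sample so the filter starts in steady state for a
#' constant-start series; the moving average uses an expanding mean
#' during its 5 s warm-up.
#'
#' @param recording An [hb_recording()] at 10 Hz (or any rate; cutoffs
#'   are in Hz). Series must be longer than 5 s.
#' @return The filtered recording (same class and metadata).
#' @export
device_preprocess <- function(recording) {
  stopifnot(inherits(recording, "hb_recording"))
  fs <- recording$sample_rate
  if (n_samples(recording) <= 5 * fs)
    stop("recording shorter than the 5 s moving-average window")
  hp <- signal::butter(2, 0.01 / (fs / 2), type = "high")
  lp <- signal::butter(2, 1 / (fs / 2), type = "low")
  w <- round(5 * fs)
  fil <- function(x) {
    y <- signal::filter(hp, x - x[1])
    y <- signal::filter(lp, y)
    # causal moving average via cumulative sums, expanding-mean warm-up
    cs <- cumsum(y)
    n <- length(y)
    ma <- numeric(n)
    head_idx <- seq_len(min(w, n))
    ma[head_idx] <- cs[head_idx] / head_idx
    if (n > w) {
      idx <- (w + 1):n
      ma[idx] <- (cs[idx] - cs[idx - w]) / w
    }
    ma
  }
  recording$hbo <- apply(recording$hbo, 2, fil)
  recording$hbr <- apply(recording$hbr, 2, fil)
  recording
}

#' Per-trial CBSI parameters from the pre-regulation window
#'
#' Estimates, from the no-regulation window immediately preceding a
#' regulation trial (its last 30 s, or the full window when the
#' no-regulation period is shorter), the offsets (window means of HbO
#' and HbR) and the noise-amplitude ratio alpha = sd(HbO)/sd(HbR) used
#' by the correlation-based signal improvement.
#'
#' @param pre_window_hbo,pre_window_hbr Equal-length numeric vectors
#'   covering the pre-regulation estimation window.
#' @return A list with `alpha`, `hbo_offset`, `hbr_offset` and a
#'   `degenerate` flag (TRUE when sd(HbR) = 0, in which case alpha
#'   falls back to 1).
#' @export
estimate_trial_params <- function(pre_window_hbo, pre_window_hbr) {
  if (length(pre_window_hbo) != length(pre_window_hbr))
    stop("pre-regulation windows must have equal length")
  sd_o <- stats::sd(pre_window_hbo)
  sd_r <- stats::sd(pre_window_hbr)
  degenerate <- !is.finite(sd_r) || sd_r == 0
  alpha <- if (degenerate) 1 else sd_o / sd_r
  list(alpha = alpha,
       hbo_offset = mean(pre_window_hbo),
       hbr_offset = mean(pre_window_hbr),
       degenerate = degenerate)
}

#' Correlation-based signal improvement (CBSI)
#'
#' Motion-corrected HbO under the assumption that neural HbO and HbR
#' are maximally anticorrelated while motion moves both together:
#' `(x - alpha * y) / 2`, applied per sample to offset-corrected HbO
#' (`x`) and HbR (`y`).
#'
#' @param x Offset-corrected HbO value(s).
#' @param y Offset-corrected HbR value(s).
#' @param alpha Noise-amplitude ratio sd(HbO)/sd(HbR), positive.
#' @return Corrected value(s), vectorised.
#' @examples
#' cbsi_correct(1, -1, 1)  # perfect anticorrelation preserves x
#' @export
cbsi_correct <- function(x, y, alpha) {
  (x - alpha * y) / 2
}

#' Baseline normalisation of the corrected signal
#'
#' Normalises the CBSI-corrected signal relative to the HbO signal from
#' the last 5 s of the preceding no-regulation period:
#' `(x_corr - md(baseline)) / sd(baseline)`, with `md` the baseline
#' median (the default reading) or mean.
#'
#' @param x_corr Corrected value(s) from [cbsi_correct()].
#' @param baseline_hbo HbO samples of the 5 s baseline window.
#' @param md Centring statistic, `"median"` or `"mean"`.
#' @return A list with `signal` (normalised values) and a `degenerate`
#'   flag (TRUE when the baseline sd is 0; a machine-epsilon guard is
#'   then used so the result stays finite).
#' @export
normalize_feedback <- function(x_corr, baseline_hbo,
                               md = c("median", "mean")) {
  md <- match.arg(md)
  ctr <- if (md == "median") stats::median(baseline_hbo) else mean(baseline_hbo)
  s <- stats::sd(baseline_hbo)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) s <- .Machine$double.eps
  list(signal = (x_corr - ctr) / s, degenerate = degenerate)
}

#' Display smoothing of the feedback signal
#'
#' The displayed value ramps toward each new target over 1 s: at every
#' 100 ms update the display moves by the fraction of the remaining
#' distance that 100 ms covers of the 1 s ramp. A constant input is a
#' fixed point; a step input reaches its target no earlier than one
#' ramp length after the step.
#'
#' @param x Feedback-signal series at `sample_rate`.
#' @param sample_rate Sampling rate in Hz.
#' @param ramp_s Ramp length in seconds.
#' @return Smoothed series, same length, starting at `x[1]`.
#' @export
smooth_feedback <- function(x, sample_rate = 10, ramp_s = 1) {
  if (length(x) == 0) return(x)
  beta <- min(1, 1 / (ramp_s * sample_rate))
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in seq_along(x)[-1]) y[i] <- y[i - 1] + beta * (x[i] - y[i - 1])
  y
}

#' Threshold state of the feedback mapping
#'
#' @param T Individual threshold in feedback-signal units (> 0).
#' @param k Scaling fraction; starts at 0.25 and steps by 0.25.
#' @param reward_level Level that must be exceeded for reward (5).
#' @param reward_rate Monetary reward in EUR per second above level.
#' @return A list of class `threshold_state`.
#' @export
threshold_state <- function(T = 1, k = 0.25, reward_level = 5,
                            reward_rate = 0.01) {
  if (T <= 0) stop("`T` must be positive")
  if (k <= 0) stop("`k` must be positive")
  structure(list(T = T, k = k, reward_level = reward_level,
                 reward_rate = reward_rate),
            class = "threshold_state")
}

#' Map the feedback signal onto the 0-10 display scale
#'
#' `raw = 10 * signal / (k * T)`, negated for the downregulation
#' direction, clamped to `[0, 10]`. The avatar image index is the
#' round-half-up integer of the clamped value (11 images, levels 0-10);
#' reward is on strictly above level 5.
#'
#' @param signal Feedback-signal value(s).
#' @param state A [threshold_state()].
#' @param direction `"up"` or `"down"`.
#' @return A list with `feedback_value` (clamped, in `[0, 10]`),
#'   `image_index` (integer 0-10) and `reward_on` (logical).
#' @export
map_feedback <- function(signal, state, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(state, "threshold_state"))
  raw <- 10 * signal / (state$k * state$T)
  if (direction == "down") raw <- -raw
  fv <- pmin(10, pmax(0, raw))
  list(feedback_value = fv,
       image_index = as.integer(floor(fv + 0.5)),
       reward_on = fv > state$reward_level)
}

#' Monetary reward earned in one regulation trial
#'
#' 0.01 EUR per second spent above the reward level; at 10 Hz each
#' reward-on sample is worth 0.001 EUR, capping a 30 s trial at 0.30
#' EUR.
#'
#' @param reward_on Logical vector of per-sample reward flags.
#' @param sample_rate Sampling rate in Hz.
#' @param reward_rate EUR per second above level.
#' @return EUR earned in the trial.
#' @export
accrue_reward <- function(reward_on, sample_rate = 10, reward_rate = 0.01) {
  sum(reward_on) / sample_rate * reward_rate
}

#' Initial individual threshold from pre-assessment contrasts
#'
#' T is the mean of the participant's two pre-assessment activation
#' contrasts (invalid - valid cueing; perspective - no perspective
#' taking). If that mean is not positive, only the positive contrast is
#' used; if both contrasts are negative, T defaults to 1.
#'
#' @param contrast_attention Invalid-minus-valid activation contrast.
#' @param contrast_vpt Perspective-minus-no-perspective contrast.
#' @return The initial threshold T (> 0 unless both inputs are 0).
#' @export
initial_threshold <- function(contrast_attention, contrast_vpt) {
  stopifnot(is.finite(contrast_attention), is.finite(contrast_vpt))
  m <- mean(c(contrast_attention, contrast_vpt))
  if (m > 0) return(m)
  pos <- c(contrast_attention, contrast_vpt)
  pos <- pos[pos > 0]
  if (length(pos) > 0) pos[1] else 1
}

#' Between-run adaptation of the scaling fraction k
#'
#' After a completed run, k is incremented by 0.25 for the next run if
#' the participant exceeded feedback level 5 for at least 75% of the
#' run's regulation time (pooled over the run's trials).
#'
#' @param feedback_values Feedback values of all regulation samples of
#'   the completed run, pooled across its trials.
#' @param state The current [threshold_state()].
#' @param frac_required Required fraction of time above level (0.75).
#' @return The updated state, with attribute `"fraction"` recording the
#'   observed fraction.
#' @export
adapt_k <- function(feedback_values, state, frac_required = 0.75) {
  stopifnot(inherits(state, "threshold_state"))
  frac <- mean(feedback_values > state$reward_level)
  if (frac >= frac_required) state$k <- state$k + 0.25
  attr(state, "fraction") <- frac
  state
}

# --- internal: per-trial chain shared by the online engine and the ---
# --- offline re-analyses ---------------------------------------------
# hbo/hbr: full-length device-filtered feedback-channel series.
# Returns per-trial list(signal, params, baseline_degenerate).
trial_feedback_signals <- function(hbo, hbr, schedule, sample_rate,
                                   md = "median") {
  reg <- schedule[schedule$condition == "regulation", ]
  noreg <- schedule[schedule$condition == "no_regulation", ]
  fs <- sample_rate
  out <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    t0 <- reg$onset[i]
    pre_dur <- noreg$duration[noreg$run == reg$run[i] &
                              noreg$block == reg$block[i]]
    w <- min(30, pre_dur)
    i_on <- floor(t0 * fs) + 1
    pre_idx <- (i_on - round(w * fs)):(i_on - 1)
    base_idx <- (i_on - round(5 * fs)):(i_on - 1)
    reg_idx <- i_on:(i_on + round(reg$duration[i] * fs) - 1)
    if (pre_idx[1] < 1 || max(reg_idx) > length(hbo))
      stop("schedule extends outside the recording")
    pars <- estimate_trial_params(hbo[pre_idx], hbr[pre_idx])
    x <- hbo[reg_idx] - pars$hbo_offset
    y <- hbr[reg_idx] - pars$hbr_offset
    xc <- cbsi_correct(x, y, pars$alpha)
    nf <- normalize_feedback(xc, hbo[base_idx], md = md)
    sm <- smooth_feedback(nf$signal, sample_rate = fs)
    out[[i]] <- list(signal = sm, params = pars,
                     baseline_degenerate = nf$degenerate,
                     run = reg$run[i], day = reg$day[i],
                     block = reg$block[i], trial = reg$trial[i],
                     onset = t0)
  }
  out
}

#' Run the closed-loop feedback engine over a recorded session
#'
#' Replays the full online procedure on a recording spanning the
#' schedule: the stream is device-filtered, and for each regulation
#' trial the CBSI parameters are estimated from the preceding
#' no-regulation window, the corrected signal is normalised to the last
#' 5 s baseline, smoothed over 1 s, mapped onto the 0-10 scale under
#' the current k and T, and the monetary reward accrued; k adapts
#' between runs.
#'
#' @param recording An [hb_recording()] with a feedback channel,
#'   spanning the schedule.
#' @param schedule An [build_schedule()] event schedule.
#' @param direction `"up"` or `"down"`.
#' @param state Initial [threshold_state()].
#' @param md Baseline centring statistic (`"median"` or `"mean"`).
#' @param preprocess Apply [device_preprocess()] first (TRUE for raw
#'   device exports; set FALSE if the recording is already filtered).
#' @param keep_traces Keep the per-sample trial traces (set FALSE in
#'   bulk simulation studies that only need the trial summaries).
#' @return An object of class `nf_session`: `trials` (one row per
#'   regulation trial with `run`, `day`, `trial`, `median`, `sd`,
#'   `earned`, `k`, `T`, `alpha` and degeneracy flags), `traces` (per
#'   trial data frames of `t`, `feedback_signal`, `feedback_value`,
#'   `image_index`, `reward_on`), `k_history` (per run), the final
#'   `state` and the `direction`.
#' @export
run_closed_loop <- function(recording, schedule,
                            direction = c("up", "down"),
                            state = threshold_state(),
                            md = c("median", "mean"),
                            preprocess = TRUE, keep_traces = TRUE) {
  direction <- match.arg(direction)
  md <- match.arg(md)
  validate_schedule(schedule)
  stopifnot(inherits(recording, "hb_recording"))
  fs <- recording$sample_rate
  if (max(schedule$onset + schedule$duration) * fs > n_samples(recording) + 1e-6)
    stop("recording does not span the schedule")
  if (preprocess) recording <- device_preprocess(recording)
  j <- fb_index(recording)
  hbo <- recording$hbo[, j]
  hbr <- recording$hbr[, j]

  sigs <- trial_feedback_signals(hbo, hbr, schedule, fs, md = md)
  runs <- sort(unique(vapply(sigs, `[[`, 0, "run")))
  traces <- vector("list", length(sigs))
  rows <- vector("list", length(sigs))
  k_hist <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    idx <- which(vapply(sigs, `[[`, 0, "run") == r)
    run_fv <- numeric(0)
    for (i in idx) {
      s <- sigs[[i]]
      mp <- map_feedback(s$signal, state, direction)
      earned <- accrue_reward(mp$reward_on, sample_rate = fs,
                              reward_rate = state$reward_rate)
      if (keep_traces) {
        traces[[i]] <- data.frame(
          t = s$onset + (seq_along(s$signal) - 1) / fs,
          feedback_signal = s$signal,
          feedback_value = mp$feedback_value,
          image_index = mp$image_index,
          reward_on = mp$reward_on
        )
        attr(traces[[i]], "trial") <- s$trial
        attr(traces[[i]], "earned") <- earned
      }
      rows[[i]] <- list(
        run = s$run, day = s$day, block = s$block, trial = s$trial,
        median = stats::median(s$signal), sd = stats::sd(s$signal),
        earned = earned, k = state$k, T = state$T,
        alpha = s$params$alpha,
        alpha_degenerate = s$params$degenerate,
        baseline_degenerate = s$baseline_degenerate
      )
      run_fv <- c(run_fv, mp$feedback_value)
    }
    new_state <- adapt_k(run_fv, state)
    k_hist[[ri]] <- data.frame(run = r, k_before = state$k,
                               k_after = new_state$k,
                               fraction_above = attr(new_state, "fraction"))
    state <- new_state
  }
  structure(list(
    trials = do.call(rbind, lapply(rows, as.data.frame)),
    traces = if (keep_traces) traces else NULL,
    k_history = do.call(rbind, k_hist),
    state = state,
    direction = direction,
    md = md
  ), class = "nf_session")
}

#' @export
print.nf_session <- function(x, ...) {
  cat("<nf_session> direction=", x$direction, ", ",
      nrow(x$trials), " regulation trials over ",
      length(unique(x$trials$run)), " runs\n", sep = "")
  cat("  total earned: ", sprintf("%.2f EUR", sum(x$trials$earned)),
      "; final k = ", x$state$k, "\n", sep = "")
  invisible(x)
}
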