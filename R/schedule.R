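# Session configuration and block-schedule construction.
#
# A full training comprises 12 neurofeedback runs spread over 4 days as
# (2, 4, 4, 2). Each run has 6 blocks; a block is a 25 s or 30 s
# no-regulation period, a 30 s regulation period, and a 2 s reward
# display. No-regulation durations are jittered to avoid phase-locking
# with slow physiology (breathing, Mayer waves).

#' Session configuration for a neurofeedback training
#'
#' Collects every tunable of the closed-loop protocol with the standard
#' training as default: 12 runs over 4 days as (2, 4, 4, 2), 6 blocks
#' per run, 30 s regulation preceded by a jittered 25 s/30 s
#' no-regulation period and followed by a 2 s reward display, sampled at
#' 10 Hz, initial scaling fraction k = 0.25 (stepping by 0.25), reward
#' level 5 and reward rate 0.01 EUR per second above level.
#'
#' @param direction Regulation direction, `"up"` or `"down"`.
#' @param k0 Initial scaling fraction k (level 10 corresponds to k*T).
#' @param threshold Individual threshold T in feedback-signal units, or
#'   `"auto"` to derive it from pre-assessment contrasts elsewhere.
#' @param runs_per_day Integer vector of runs per training day.
#' @param blocks_per_run Blocks (trials) per run.
#' @param regulation_s Regulation period duration in seconds.
#' @param no_regulation_s Candidate no-regulation durations in seconds.
#' @param reward_display_s Reward display duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param reward_rate Monetary reward in EUR per second above level 5.
#' @param reward_level Feedback level that must be exceeded for reward.
#' @param md Interpretation of the baseline centring statistic
#'   (`"median"` or `"mean"`).
#' @param jitter `"balanced"` draws no-regulation durations balanced
#'   within each run (3 of each for 6 blocks); `"random"` draws freely.
#' @return A list of class `session_config`.
#' @export
session_config <- function(direction = c("up", "down"),
                           k0 = 0.25,
                           threshold = 1,
                           runs_per_day = c(2L, 4L, 4L, 2L),
                           blocks_per_run = 6L,
                           regulation_s = 30,
                           no_regulation_s = c(25, 30),
                           reward_display_s = 2,
                           sample_rate = 10,
                           reward_rate = 0.01,
                           reward_level = 5,
                           md = c("median", "mean"),
                           jitter = c("balanced", "random")) {
  direction <- match.arg(direction)
  md <- match.arg(md)
  jitter <- match.arg(jitter)
  if (any(c(regulation_s, no_regulation_s, reward_display_s) <= 0))
    stop("all durations must be positive")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  structure(list(
    direction = direction, k0 = k0, threshold = threshold,
    runs_per_day = as.integer(runs_per_day),
    blocks_per_run = as.integer(blocks_per_run),
    regulation_s = regulation_s, no_regulation_s = no_regulation_s,
    reward_display_s = reward_display_s, sample_rate = sample_rate,
    reward_rate = reward_rate, reward_level = reward_level,
    md = md, jitter = jitter
  ), class = "session_config")
}

#' Build the event schedule of a full neurofeedback training
#'
#' Lays out every run, block and condition interval on one continuous
#' time axis (seconds from recording start). The no-regulation duration
#' of each block is drawn pseudo-randomly from the configured candidates
#' (balanced within each run by default) so that slow physiological
#' rhythms cannot synchronise with the block structure.
#'
#' @param config A [session_config()].
#' @param seed Integer seed controlling the jitter; identical seeds give
#'   identical schedules.
#' @return A data frame of class `event_schedule` with columns `run`,
#'   `day`, `block`, `condition` (`no_regulation`, `regulation`,
#'   `reward`), `onset`, `duration` and, on regulation rows, the global
#'   `trial` index.
#' @examples
#' sched <- build_schedule(session_config(), seed = 1)
#' table(sched$condition)
#' @export
build_schedule <- function(config = session_config(), seed = 1L) {
  stopifnot(inherits(config, "session_config"))
  n_runs <- sum(config$runs_per_day)
  nb <- config$blocks_per_run
  set.seed(seed)
  rows <- vector("list", n_runs)
  t0 <- 0
  trial <- 0L
  day_of_run <- rep(seq_along(config$runs_per_day), config$runs_per_day)
  for (r in seq_len(n_runs)) {
    durs <- config$no_regulation_s
    if (config$jitter == "balanced" && length(durs) > 1) {
      reps <- rep(durs, length.out = nb)
      noreg <- sample(reps)
    } else {
      noreg <- sample(durs, nb, replace = TRUE)
    }
    blk <- vector("list", nb)
    for (b in seq_len(nb)) {
      trial <- trial + 1L
      onsets <- t0 + cumsum(c(0, noreg[b], config$regulation_s))
      blk[[b]] <- data.frame(
        run = r, day = day_of_run[r], block = b,
        condition = c("no_regulation", "regulation", "reward"),
        onset = onsets,
        duration = c(noreg[b], config$regulation_s, config$reward_display_s),
        trial = c(NA_integer_, trial, NA_integer_)
      )
      t0 <- onsets[3] + config$reward_display_s
    }
    rows[[r]] <- do.call(rbind, blk)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sample_rate") <- config$sample_rate
  attr(out, "seed") <- seed
  class(out) <- c("event_schedule", "data.frame")
  validate_schedule(out)
  out
}

#' Validate an event schedule
#'
#' Checks ordering, non-overlap and the protocol's duration contracts
#' (regulation exactly 30 s by default; no-regulation within the
#' configured candidates).
#'
#' @param schedule An `event_schedule` data frame.
#' @return The schedule, invisibly; stops on violation.
#' @export
validate_schedule <- function(schedule) {
  req <- c("run", "day", "block", "condition", "onset", "duration")
  if (!all(req %in% names(schedule)))
    stop("schedule lacks required columns: ",
         paste(setdiff(req, names(schedule)), collapse = ", "))
  if (is.unsorted(schedule$onset, strictly = TRUE))
    stop("schedule onsets must be strictly increasing")
  ends <- schedule$onset + schedule$duration
  if (any(schedule$onset[-1] < ends[-length(ends)] - 1e-9))
    stop("schedule intervals overlap")
  if (any(schedule$duration <= 0)) stop("schedule durations must be positive")
  invisible(schedule)
}

#' Total regulation time of a schedule
#'
#' @param schedule An `event_schedule`.
#' @return Total regulation time in seconds (36 min = 2160 s for the
#'   default 12-run training).
#' @export
total_regulation_time <- function(schedule) {
  sum(schedule$duration[schedule$condition == "regulation"])
}
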