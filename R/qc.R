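# Offline channel quality control: coefficient-of-variation screening,
# flat-line detection, manual re-inclusion with an audit trail, trial
# interpolation, and outlier-sample replacement.

#' Coefficient of variation of a series
#'
#' `100 * sd(x) / |mean(x)|`, in percent, computed on the series as
#' supplied (i.e. the device export carrying its DC level; CoV is
#' undefined on mean-removed data). Channels whose |mean| falls below
#' `eps` cannot be screened automatically and return `NA` so they can
#' be routed to manual review.
#'
#' @param x Non-empty numeric series.
#' @param eps Smallest |mean| for which CoV is considered defined.
#' @return CoV in percent, or `NA` when undefined.
#' @export
coefficient_of_variation <- function(x, eps = 1e-8) {
  if (length(x) == 0) stop("`x` must be non-empty")
  m <- mean(x)
  if (!is.finite(m) || abs(m) < eps) return(NA_real_)
  100 * stats::sd(x) / abs(m)
}

# length of the longest run of exactly-identical consecutive samples
longest_flat_run <- function(x) {
  if (length(x) < 2) return(length(x))
  r <- rle(diff(x) == 0)
  flat <- r$lengths[r$values]
  if (length(flat) == 0) 1L else max(flat) + 1L
}

#' Detect bad channels
#'
#' Screens every channel of a recording: a channel is excluded when its
#' CoV exceeds `cov_limit` (default 10%) in HbO or HbR, when the CoV
#' difference between the chromophores exceeds `cov_diff_limit`
#' (default 5 percentage points), or when either chromophore contains a
#' flat line of at least `flat_s` seconds (>= 10 bitwise-identical
#' consecutive samples at 10 Hz). Channels with an undefined CoV are
#' flagged for manual review, not auto-excluded.
#'
#' @param recording An [hb_recording()] (raw device export).
#' @param cov_limit CoV exclusion limit in percent.
#' @param cov_diff_limit Chromophore CoV-difference limit in points.
#' @param flat_s Minimal flat-line duration in seconds.
#' @return A list of class `qc_report` with a per-channel data frame
#'   (`channel`, `cov_hbo`, `cov_hbr`, `cov_diff`, `flatline_found`,
#'   `excluded`, `reincluded`, `manual_review`, `reason`) and an empty
#'   audit log.
#' @export
detect_bad_channels <- function(recording, cov_limit = 10,
                                cov_diff_limit = 5, flat_s = 1) {
  stopifnot(inherits(recording, "hb_recording"))
  fs <- recording$sample_rate
  min_flat <- round(flat_s * fs)
  chans <- recording$channels$channel
  rows <- lapply(seq_along(chans), function(j) {
    co <- coefficient_of_variation(recording$hbo[, j])
    cr <- coefficient_of_variation(recording$hbr[, j])
    fl <- longest_flat_run(recording$hbo[, j]) >= min_flat ||
          longest_flat_run(recording$hbr[, j]) >= min_flat
    manual <- is.na(co) || is.na(cr)
    cd <- if (manual) NA_real_ else abs(co - cr)
    reasons <- character(0)
    if (!manual) {
      if (co > cov_limit) reasons <- c(reasons, "cov_hbo")
      if (cr > cov_limit) reasons <- c(reasons, "cov_hbr")
      if (cd > cov_diff_limit) reasons <- c(reasons, "cov_diff")
    }
    if (fl) reasons <- c(reasons, "flatline")
    if (manual) reasons <- c(reasons, "cov_undefined")
    data.frame(channel = chans[j], cov_hbo = co, cov_hbr = cr,
               cov_diff = cd, flatline_found = fl,
               excluded = length(setdiff(reasons, "cov_undefined")) > 0,
               reincluded = FALSE, manual_review = manual,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  structure(list(channels = do.call(rbind, rows), audit = list()),
            class = "qc_report")
}

#' Re-include an excluded channel after visual inspection
#'
#' Records a justified manual override: the channel is marked
#' re-included and treated as good downstream. Re-including a channel
#' twice is idempotent (one audit entry); re-including a channel that
#' was never excluded is an error.
#'
#' @param report A `qc_report` from [detect_bad_channels()].
#' @param channel Channel id to re-include.
#' @param justification Non-empty free-text justification.
#' @return The updated report.
#' @export
reinclude_channel <- function(report, channel, justification) {
  stopifnot(inherits(report, "qc_report"))
  if (missing(justification) || !nzchar(trimws(justification)))
    stop("a non-empty justification is required")
  j <- match(channel, report$channels$channel)
  if (is.na(j)) stop("unknown channel: ", channel)
  if (!report$channels$excluded[j])
    stop("channel ", channel, " is not excluded")
  if (report$channels$reincluded[j]) return(report)
  report$channels$reincluded[j] <- TRUE
  report$audit[[length(report$audit) + 1]] <-
    list(channel = channel, action = "reinclude",
         justification = justification)
  report
}

#' Channels usable downstream
#'
#' @param report A `qc_report`.
#' @return Character vector of channels that are not excluded, or were
#'   excluded but re-included.
#' @export
good_channels <- function(report) {
  ch <- report$channels
  ch$channel[!ch$excluded | ch$reincluded]
}

#' Replace a bad trial by the mean of its neighbours
#'
#' A trial flagged as unusable is replaced by the sample-wise mean of
#' its six neighbouring trials: up to 3 preceding and 3 following,
#' truncated at the edges of the trial sequence.
#'
#' @param trials List of equal-length numeric vectors (one per trial,
#'   in temporal order).
#' @param index Index of the trial to replace.
#' @return The replacement series.
#' @export
interpolate_bad_trials <- function(trials, index) {
  n <- length(trials)
  if (index < 1 || index > n) stop("`index` out of range")
  nb <- setdiff(intersect((index - 3):(index + 3), seq_len(n)), index)
  if (length(nb) == 0) stop("trial has no neighbouring trials")
  mat <- do.call(rbind, trials[nb])
  colMeans(mat)
}

#' Replace within-trial outlier samples
#'
#' Samples deviating more than 3 standard deviations from the trial
#' mean (mean and sd computed once, on the original trial) are replaced
#' by the last retained observation (LOCF); a leading outlier takes the
#' next retained sample instead.
#'
#' @param x Trial series (length >= 2).
#' @param n_sd Deviation limit in trial standard deviations.
#' @return A list with `series` (cleaned) and `n_replaced`.
#' @export
remove_outlier_samples <- function(x, n_sd = 3) {
  if (length(x) < 2) stop("trial series must have length >= 2")
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(list(series = x, n_replaced = 0L))
  out <- abs(x - m) > n_sd * s
  if (!any(out)) return(list(series = x, n_replaced = 0L))
  y <- x
  kept <- which(!out)
  if (length(kept) == 0) stop("all samples are outliers; nothing to carry")
  for (i in which(out)) {
    prev <- kept[kept < i]
    if (length(prev) > 0) y[i] <- y[max(prev)]
    else y[i] <- x[min(kept)]
  }
  list(series = y, n_replaced = sum(out))
}
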