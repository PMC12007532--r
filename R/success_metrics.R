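# Neurofeedback success measures: run-level success, participant
# classification (maintenance, improvement by slope and by
# last-vs-first session, amplitude and variability), group-level
# t-tests with Cohen's d, the noncentral-t sensitivity analysis, and
# Bonferroni-corrected Spearman correlations.

#' Summarise one neurofeedback run
#'
#' Computes the per-trial median and standard deviation of the feedback
#' signal for the run's six regulation trials and classifies the run:
#' successful iff the median of the six trial medians is strictly
#' positive (upregulation) or strictly negative (downregulation); an
#' exact zero counts as unsuccessful.
#'
#' @param trial_signals List of the run's per-trial feedback-signal
#'   vectors (6 after QC interpolation).
#' @param direction `"up"` or `"down"`.
#' @param run_index,session_index Optional indices carried through.
#' @param n_trials Expected trial count per run.
#' @return A one-row data frame of class `run_summary` with
#'   `trial_medians` and `trial_sds` attached as attributes.
#' @export
summarize_run <- function(trial_signals, direction = c("up", "down"),
                          run_index = NA_integer_,
                          session_index = NA_integer_,
                          n_trials = 6L) {
  direction <- match.arg(direction)
  if (length(trial_signals) != n_trials)
    stop("expected ", n_trials, " trials, got ", length(trial_signals))
  meds <- vapply(trial_signals, stats::median, 0)
  sds <- vapply(trial_signals, stats::sd, 0)
  centre <- stats::median(meds)
  out <- data.frame(
    run = run_index, session = session_index,
    run_mean_median = mean(meds), run_mean_sd = mean(sds),
    successful = if (direction == "up") centre > 0 else centre < 0
  )
  attr(out, "trial_medians") <- meds
  attr(out, "trial_sds") <- sds
  class(out) <- c("run_summary", "data.frame")
  out
}

#' Summarise all runs of a session's trial table
#'
#' Aggregates a per-trial summary table (as produced by
#' [run_closed_loop()] or [offline_reanalysis()]) into one row per run:
#' mean of trial medians, mean of trial SDs, and the run's success
#' classification.
#'
#' @param trials Data frame with columns `run`, `median`, `sd` and
#'   optionally `day`.
#' @param direction `"up"` or `"down"`.
#' @return Data frame with one row per run: `run`, `session`,
#'   `run_mean_median`, `run_mean_sd`, `successful`.
#' @export
summarize_runs <- function(trials, direction = c("up", "down")) {
  direction <- match.arg(direction)
  runs <- sort(unique(trials$run))
  do.call(rbind, lapply(runs, function(r) {
    tr <- trials[trials$run == r, ]
    centre <- stats::median(tr$median)
    data.frame(
      run = r,
      session = if ("day" %in% names(tr)) tr$day[1] else NA_integer_,
      run_mean_median = mean(tr$median),
      run_mean_sd = mean(tr$sd),
      successful = if (direction == "up") centre > 0 else centre < 0
    )
  }))
}

#' Classify a participant's regulation success
#'
#' Applies the individual-level success hierarchy to a participant's 12
#' run summaries: maintenance (classified successful iff more than 50%
#' of runs were successful, i.e. at least 7 of 12), improvement as the
#' OLS slope of the run means over run index (success iff its sign
#' matches the regulation direction), and improvement as the
#' last-vs-first session difference, mean(runs 11, 12) - mean(runs 1,
#' 2) (sign-matched likewise). Variability analogues are computed on
#' the run means of the trial SDs; decreasing variability (negative
#' slope / difference) counts as successful in both groups.
#'
#' @param runs Data frame from [summarize_runs()] (one row per run).
#' @param direction `"up"` or `"down"`.
#' @param partial Allow fewer than 12 runs (classification then uses
#'   >50% of the retained runs and the first/last two retained runs).
#' @return A list of class `participant_summary`.
#' @export
classify_participant <- function(runs, direction = c("up", "down"),
                                 partial = FALSE) {
  direction <- match.arg(direction)
  runs <- runs[order(runs$run), ]
  n <- nrow(runs)
  if (n != 12 && !partial)
    stop("expected 12 runs (got ", n, "); set `partial = TRUE` for ",
         "incomplete trainings")
  if (n < 4) stop("need at least 4 runs")
  sign_ok <- function(v) if (direction == "up") v > 0 else v < 0

  n_succ <- sum(runs$successful)
  slope <- unname(stats::lsfit(runs$run, runs$run_mean_median)$coefficients[2])
  lvf <- mean(runs$run_mean_median[(n - 1):n]) -
    mean(runs$run_mean_median[1:2])
  var_slope <- unname(stats::lsfit(runs$run, runs$run_mean_sd)$coefficients[2])
  var_lvf <- mean(runs$run_mean_sd[(n - 1):n]) - mean(runs$run_mean_sd[1:2])
  structure(list(
    direction = direction,
    n_runs = n,
    n_successful_runs = n_succ,
    classified_successful = n_succ / n > 0.5,
    slope = slope,
    slope_successful = sign_ok(slope),
    last_vs_first = lvf,
    last_vs_first_successful = sign_ok(lvf),
    var_slope = var_slope,
    var_slope_successful = var_slope < 0,
    var_last_vs_first = var_lvf,
    var_last_vs_first_successful = var_lvf < 0,
    mean_over_runs = mean(runs$run_mean_median)
  ), class = "participant_summary")
}

#' Group-level maintenance test
#'
#' One-sample t-test of the participants' mean regulation effects
#' against zero (two-sided), with Cohen's d = mean/sd.
#'
#' @param x Per-participant mean feedback signal over all runs.
#' @return A list with `t`, `df`, `p`, `d`, `mean`, `sd`, `n`.
#' @export
group_maintenance_test <- function(x) {
  if (length(x) < 2) stop("need at least 2 participants")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance; t-test undefined")
  tt <- stats::t.test(x, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(x) / s, mean = mean(x), sd = s,
       n = length(x))
}

#' Group-level change test (last vs first session)
#'
#' Paired t-test of last-session against first-session regulation
#' means, with Cohen's d on the differences (mean(diff)/sd(diff),
#' diff = last - first).
#'
#' @param first,last Equal-length per-participant session means.
#' @return A list with `t`, `df`, `p`, `d`, `mean_diff`, `sd_diff`,
#'   `n`.
#' @export
group_change_test <- function(first, last) {
  if (length(first) != length(last)) stop("paired vectors differ in length")
  d <- last - first
  s <- stats::sd(d)
  if (s == 0) stop("zero difference variance; paired t-test undefined")
  tt <- stats::t.test(last, first, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / s, mean_diff = mean(d),
       sd_diff = s, n = length(d))
}

#' Minimal detectable effect size of an independent-samples t-test
#'
#' Solves, by bisection on Cohen's d, for the smallest standardised
#' effect an independent-samples t-test detects with the requested
#' power, using the noncentral t distribution with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of
#' freedom.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Significance level.
#' @param power Target power (must exceed `alpha`).
#' @param sides 1 (one-sided, default) or 2.
#' @param tol Bisection tolerance on d.
#' @return Minimal detectable Cohen's d.
#' @examples
#' sensitivity_min_effect(27, 18, alpha = 0.05, power = 0.80)
#' @export
sensitivity_min_effect <- function(n1, n2, alpha = 0.05, power = 0.80,
                                   sides = 1, tol = 1e-8) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)")
  if (power <= alpha) stop("`power` must exceed `alpha`")
  if (!sides %in% c(1, 2)) stop("`sides` must be 1 or 2")
  df <- n1 + n2 - 2
  ncf <- sqrt(n1 * n2 / (n1 + n2))
  pw <- function(d) {
    ncp <- d * ncf
    if (sides == 1) {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
    }
  }
  lo <- 0
  hi <- 1
  while (pw(hi) < power) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Spearman correlation with Bonferroni correction
#'
#' Tie-corrected Spearman rank correlation (Pearson correlation of the
#' midranks) with the asymptotic p-value and a Bonferroni adjustment
#' for a family of `m` tests.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param m Family size for the Bonferroni correction.
#' @return A list with `rho`, `p_raw`, `p_adjusted`, `n`, `m`, and a
#'   `degenerate` flag (TRUE when either vector is constant; `rho` is
#'   then `NA`).
#' @export
spearman_bonferroni <- function(x, y, m = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (m < 1) stop("`m` must be >= 1")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
                n = length(x), m = m, degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_raw = ct$p.value,
       p_adjusted = min(1, m * ct$p.value), n = length(x), m = m,
       degenerate = FALSE)
}
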