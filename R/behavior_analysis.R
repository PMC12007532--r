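# Behavioural pipeline: RT filtering, harmonic means, the reorienting
# (invalidity) effect from invalid blocks, vPT accuracy/RT summaries,
# and pre/post group-effect descriptives with Cohen's d and Welch
# t-tests.

#' Filter attention-task trials
#'
#' Retains, among attention-task rows, only correct trials with
#' 100 <= RT <= 1000 ms (the printed limits "<100" and ">1000" are
#' strict, so the boundary values are kept). Rows of other tasks pass
#' through untouched. Filtering is idempotent.
#'
#' @param table A behaviour table (see [simulate_behavior()]).
#' @return The filtered table, with an `exclusions` attribute counting
#'   removed trials per reason (`incorrect`, `too_fast`, `too_slow`).
#' @export
filter_attention_trials <- function(table) {
  att <- table$task == "attention"
  incorrect <- att & !table$correct
  fast <- att & table$correct & table$rt < 100
  slow <- att & table$correct & table$rt > 1000
  keep <- !att | (table$correct & table$rt >= 100 & table$rt <= 1000)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(incorrect = sum(incorrect),
                               too_fast = sum(fast),
                               too_slow = sum(slow))
  out
}

#' Harmonic mean
#'
#' `n / sum(1/x)`; the recommended central-tendency estimator for
#' reaction times (less outlier-sensitive than the arithmetic mean).
#'
#' @param x Positive values (ms), n >= 1.
#' @return The harmonic mean.
#' @examples
#' harmonic_mean(c(400, 500))
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0) stop("`x` must be non-empty")
  if (any(x <= 0)) stop("harmonic mean requires strictly positive values")
  length(x) / sum(1 / x)
}

#' Reorienting (invalidity) effect
#'
#' The attentional cost of reorienting from a miscued location:
#' harmonic-mean RT of invalid trials minus harmonic-mean RT of valid
#' trials, computed from invalid blocks only (valid blocks contain no
#' invalid trials and do not enter). Positive values are reorienting
#' costs.
#'
#' @param table A filtered behaviour table.
#' @param participant,time Optional: restrict to one participant and/or
#'   time point and return the scalar effect; otherwise a data frame
#'   over all participant x time cells is returned.
#' @return Scalar effect in ms, or a data frame with columns
#'   `participant`, `time`, `hm_invalid`, `hm_valid`, `reorienting`.
#' @export
reorienting_effect <- function(table, participant = NULL, time = NULL) {
  tab <- table[table$task == "attention" &
               table$block_type == "invalid_block", , drop = FALSE]
  if (!is.null(participant)) tab <- tab[tab$participant == participant, ]
  if (!is.null(time)) tab <- tab[tab$time == time, ]
  if (nrow(tab) == 0) stop("no invalid-block attention trials selected")
  one <- function(d) {
    inv <- d$rt[d$trial_validity == "invalid"]
    val <- d$rt[d$trial_validity == "valid"]
    if (length(inv) == 0 || length(val) == 0)
      stop("both validities must be present after filtering")
    c(hm_invalid = harmonic_mean(inv), hm_valid = harmonic_mean(val))
  }
  if (!is.null(participant) && !is.null(time)) {
    h <- one(tab)
    return(unname(h["hm_invalid"] - h["hm_valid"]))
  }
  cells <- unique(tab[, c("participant", "time")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- tab[tab$participant == cells$participant[i] &
             tab$time == cells$time[i], ]
    h <- one(d)
    data.frame(participant = cells$participant[i], time = cells$time[i],
               hm_invalid = h[["hm_invalid"]], hm_valid = h[["hm_valid"]],
               reorienting = h[["hm_invalid"]] - h[["hm_valid"]])
  }))
  rownames(out) <- NULL
  out
}

#' Visual perspective-taking summaries
#'
#' Per participant x time x condition: proportion correct and
#' harmonic-mean RT over all trials (no RT window is applied to the
#' vPT task), with a ceiling flag at accuracy 1.
#'
#' @param table A behaviour table containing vPT rows.
#' @return Data frame with columns `participant`, `time`, `condition`,
#'   `accuracy`, `hm_rt`, `ceiling`.
#' @export
vpt_summaries <- function(table) {
  tab <- table[table$task == "vpt", , drop = FALSE]
  if (nrow(tab) == 0) stop("no vPT trials in the table")
  cells <- unique(tab[, c("participant", "time", "block_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- tab[tab$participant == cells$participant[i] &
             tab$time == cells$time[i] &
             tab$block_type == cells$block_type[i], ]
    acc <- mean(d$correct)
    data.frame(participant = cells$participant[i], time = cells$time[i],
               condition = cells$block_type[i], accuracy = acc,
               hm_rt = harmonic_mean(d$rt), ceiling = acc == 1)
  }))
  rownames(out) <- NULL
  out
}

#' Pre/post group-effect descriptives
#'
#' From per-participant summary values (one row per participant x
#' time): group x time cell means and SDs, within-group pre-to-post
#' changes with paired Cohen's d (mean(diff)/sd(diff)), and the Welch
#' unequal-variances t-test comparing the changes between groups.
#' Participants lacking either time point are dropped (logged in the
#' `dropped` element).
#'
#' @param summaries Data frame with columns `participant`, `group`,
#'   `time` (`pre`/`post`) and the value column.
#' @param value Name of the value column.
#' @return A list with `cells` (group x time means/SDs/n), `within`
#'   (per group: mean change, sd, paired d, t, p, n), `between` (Welch
#'   t on the changes) and `dropped` (unpaired participant ids).
#' @export
prepost_effects <- function(summaries, value = "value") {
  need <- c("participant", "group", "time", value)
  if (!all(need %in% names(summaries)))
    stop("summaries lack columns: ",
         paste(setdiff(need, names(summaries)), collapse = ", "))
  v <- summaries[[value]]
  wide <- stats::reshape(
    summaries[, c("participant", "group", "time", value)],
    idvar = c("participant", "group"), timevar = "time",
    direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  paired <- stats::complete.cases(wide[, c("pre", "post")])
  dropped <- wide$participant[!paired]
  wide <- wide[paired, ]
  if (nrow(wide) == 0) stop("no participant has both time points")

  cells <- do.call(rbind, lapply(split(summaries, list(summaries$group,
                                                       summaries$time)),
    function(d) if (nrow(d) == 0) NULL else
      data.frame(group = d$group[1], time = d$time[1],
                 mean = mean(d[[value]]), sd = stats::sd(d[[value]]),
                 n = nrow(d))))
  rownames(cells) <- NULL

  within <- do.call(rbind, lapply(split(wide, wide$group), function(d) {
    diff <- d$post - d$pre
    s <- stats::sd(diff)
    tt <- if (length(diff) >= 2 && s > 0)
      stats::t.test(d$post, d$pre, paired = TRUE) else NULL
    data.frame(group = d$group[1], mean_change = mean(diff),
               sd_change = s,
               d = if (is.finite(s) && s > 0) mean(diff) / s else 0,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               n = length(diff))
  }))
  rownames(within) <- NULL

  groups <- sort(unique(wide$group))
  between <- NULL
  if (length(groups) == 2) {
    d1 <- wide$post[wide$group == groups[1]] - wide$pre[wide$group == groups[1]]
    d2 <- wide$post[wide$group == groups[2]] - wide$pre[wide$group == groups[2]]
    wt <- stats::t.test(d1, d2)  # Welch by default
    between <- list(groups = groups, t = unname(wt$statistic),
                    df = unname(wt$parameter), p = wt$p.value,
                    diff_of_changes = mean(d1) - mean(d2))
  }
  list(cells = cells, within = within, between = between,
       dropped = dropped)
}
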