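# Behavioural generator: Posner spatial-cueing trials (12 blocks, 6
# invalid blocks of 12 valid + 8 invalid trials, 6 valid blocks of 20
# valid trials; 192/48 of 240) and visual perspective-taking (vPT)
# trials (4 trials per block, PT and NPT conditions). Reaction times
# follow a shifted lognormal matched by moments to each design cell.

#' Behavioural simulation configuration
#'
#' Holds per-cell reaction-time means and SDs and per-cell accuracy
#' rates. Defaults reproduce the baseline characteristics of the study
#' population: attention-task pre RTs (valid/invalid) and vPT pre RTs
#' (PT/NPT) per group, post values shifted by the observed across-
#' condition pre-post changes (upregulation -17 ms, downregulation
#' +15 ms for the attention task; both groups ~ -130 ms and ~ +2.5
#' accuracy points for the vPT task).
#'
#' @param cells Data frame with columns `task` (`attention`/`vpt`),
#'   `group` (`up`/`down`), `time` (`pre`/`post`), `condition`
#'   (`valid`/`invalid` or `PT`/`NPT`), `mean`, `sd` (ms).
#' @param accuracy Data frame with columns `task`, `condition`, `time`,
#'   `rate` (proportion correct in `[0, 1]`).
#' @param rt_shift Shift of the shifted-lognormal RT model in ms.
#' @param n_vpt_blocks_per_condition vPT blocks per condition (4 trials
#'   each).
#' @return A list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(cells = NULL, accuracy = NULL,
                                rt_shift = 150,
                                n_vpt_blocks_per_condition = 4L) {
  if (is.null(cells)) {
    cells <- rbind(
      expand.grid(task = "attention", group = c("up", "down"),
                  time = c("pre", "post"), condition = c("valid", "invalid"),
                  stringsAsFactors = FALSE),
      expand.grid(task = "vpt", group = c("up", "down"),
                  time = c("pre", "post"), condition = c("PT", "NPT"),
                  stringsAsFactors = FALSE)
    )
    key <- with(cells, paste(task, group, time, condition))
    mu <- c(
      "attention up pre valid" = 452, "attention up pre invalid" = 497,
      "attention down pre valid" = 468, "attention down pre invalid" = 508,
      "attention up post valid" = 435, "attention up post invalid" = 480,
      "attention down post valid" = 483, "attention down post invalid" = 523,
      "vpt up pre PT" = 3667, "vpt up pre NPT" = 3611,
      "vpt down pre PT" = 3630, "vpt down pre NPT" = 3620,
      "vpt up post PT" = 3537, "vpt up post NPT" = 3481,
      "vpt down post PT" = 3500, "vpt down post NPT" = 3490
    )
    sg <- c(
      "attention up pre valid" = 61, "attention up pre invalid" = 69,
      "attention down pre valid" = 94, "attention down pre invalid" = 90,
      "attention up post valid" = 57, "attention up post invalid" = 57,
      "attention down post valid" = 108, "attention down post invalid" = 108,
      "vpt up pre PT" = 327, "vpt up pre NPT" = 286,
      "vpt down pre PT" = 302, "vpt down pre NPT" = 272,
      "vpt up post PT" = 295, "vpt up post NPT" = 295,
      "vpt down post PT" = 295, "vpt down post NPT" = 295
    )
    cells$mean <- unname(mu[key])
    cells$sd <- unname(sg[key])
  }
  if (is.null(accuracy)) {
    accuracy <- rbind(
      data.frame(task = "attention", condition = c("valid", "invalid"),
                 time = "pre", rate = c(0.99, 0.98)),
      data.frame(task = "attention", condition = c("valid", "invalid"),
                 time = "post", rate = c(0.99, 0.98)),
      data.frame(task = "vpt", condition = c("PT", "NPT"),
                 time = "pre", rate = c(0.94, 0.98)),
      data.frame(task = "vpt", condition = c("PT", "NPT"),
                 time = "post", rate = c(0.97, 0.99))
    )
  }
  if (any(accuracy$rate < 0 | accuracy$rate > 1))
    stop("accuracy rates must lie in [0, 1]")
  if (any(cells$sd <= 0)) stop("all cell SDs must be positive")
  if (any(cells$mean <= rt_shift))
    stop("cell means must exceed the RT shift")
  structure(list(cells = cells, accuracy = accuracy, rt_shift = rt_shift,
                 n_vpt_blocks_per_condition =
                   as.integer(n_vpt_blocks_per_condition)),
            class = "behavior_sim_config")
}

# moment-matched shifted lognormal draws: mean m, sd s, shift a
rshifted_lnorm <- function(n, m, s, a) {
  mu_ <- m - a
  sig2 <- log(1 + (s / mu_)^2)
  a + stats::rlnorm(n, meanlog = log(mu_) - sig2 / 2, sdlog = sqrt(sig2))
}

.cell_lookup <- function(df, ...) {
  keys <- list(...)
  sel <- rep(TRUE, nrow(df))
  for (nm in names(keys)) sel <- sel & df[[nm]] == keys[[nm]]
  row <- df[sel, , drop = FALSE]
  if (nrow(row) != 1) stop("missing or ambiguous cell: ",
                           paste(unlist(keys), collapse = "/"))
  row
}

#' Simulate a participant's behavioural session
#'
#' Generates one measurement time point for one participant: 240
#' Posner attention trials in 12 blocks (6 invalid blocks of 12 valid
#' + 8 invalid trials, 6 valid blocks of 20 valid trials; block order
#' randomised) and the vPT task (4 trials per block, PT and NPT blocks
#' in pseudo-random order with no more than two consecutive blocks of
#' the same condition). RTs are drawn from the configured
#' shifted-lognormal cells; correctness from the configured accuracy
#' rates.
#'
#' @param config A [behavior_sim_config()].
#' @param group `"up"` or `"down"`.
#' @param time `"pre"` or `"post"`.
#' @param participant Participant id carried into the table.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `BehaviorTable` data frame with columns `participant`,
#'   `group`, `time`, `task`, `block`, `block_type`, `trial_validity`
#'   (attention) or condition (`PT`/`NPT` in `block_type` for vPT),
#'   `rt` (ms), `correct`.
#' @export
simulate_behavior <- function(config = behavior_sim_config(),
                              group = c("up", "down"),
                              time = c("pre", "post"),
                              participant = "P01", seed = NULL) {
  group <- match.arg(group)
  time <- match.arg(time)
  stopifnot(inherits(config, "behavior_sim_config"))
  if (!is.null(seed)) set.seed(seed)

  draw <- function(task, condition, n) {
    cell <- .cell_lookup(config$cells, task = task, group = group,
                         time = time, condition = condition)
    acc <- .cell_lookup(config$accuracy, task = task,
                        condition = condition, time = time)
    data.frame(
      rt = rshifted_lnorm(n, cell$mean, cell$sd, config$rt_shift),
      correct = stats::runif(n) < acc$rate
    )
  }

  # attention: 12 blocks in randomised order
  block_types <- sample(rep(c("invalid_block", "valid_block"), each = 6))
  att <- vector("list", 12)
  for (b in seq_len(12)) {
    if (block_types[b] == "invalid_block") {
      validity <- sample(rep(c("valid", "invalid"), c(12, 8)))
    } else {
      validity <- rep("valid", 20)
    }
    d <- data.frame(rt = NA_real_, correct = NA)[rep(1, length(validity)), ]
    for (v in unique(validity)) {
      sel <- validity == v
      d[sel, ] <- draw("attention", v, sum(sel))
    }
    att[[b]] <- data.frame(
      participant = participant, group = group, time = time,
      task = "attention", block = b, block_type = block_types[b],
      trial_validity = validity, rt = d$rt, correct = d$correct,
      stringsAsFactors = FALSE
    )
  }

  # vPT: PT/NPT blocks, max two consecutive of a kind
  nb <- config$n_vpt_blocks_per_condition
  repeat {
    order_ <- sample(rep(c("PT", "NPT"), each = nb))
    r <- rle(order_)
    if (all(r$lengths <= 2)) break
  }
  vpt <- vector("list", length(order_))
  for (b in seq_along(order_)) {
    d <- draw("vpt", order_[b], 4)
    vpt[[b]] <- data.frame(
      participant = participant, group = group, time = time,
      task = "vpt", block = b, block_type = order_[b],
      trial_validity = NA_character_, rt = d$rt, correct = d$correct,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(do.call(rbind, att), do.call(rbind, vpt))
  rownames(out) <- NULL
  out
}
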