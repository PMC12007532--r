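# Canonical file formats: UTF-8 tab-separated tables with a header row,
# dot decimals, times in seconds from recording start (0-based).
# Recordings are stored long (one row per sample per channel) with
# metadata in leading '#key=value' comment lines.

#' Write a recording to TSV
#'
#' Long format, one row per sample per channel with columns `time_s`,
#' `channel`, `hemisphere`, `hbo`, `hbr`; sample rate and feedback
#' channel stored as `#key=value` header comments.
#'
#' @param recording An [hb_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "hb_recording"))
  t <- recording_time(recording)
  nch <- nrow(recording$channels)
  long <- data.frame(
    time_s = rep(t, nch),
    channel = rep(recording$channels$channel, each = length(t)),
    hemisphere = rep(recording$channels$hemisphere, each = length(t)),
    hbo = as.vector(recording$hbo),
    hbr = as.vector(recording$hbr)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#sample_rate=", format(recording$sample_rate, digits = 15)),
    paste0("#feedback_channel=",
           if (is.null(recording$feedback_channel)) ""
           else recording$feedback_channel)
  ), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a recording from TSV
#'
#' @param path File written by [write_recording_tsv()].
#' @return An [hb_recording()].
#' @export
read_recording_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  getmeta <- function(key) {
    line <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(line) != 1) stop("missing metadata: ", key)
    sub(paste0("^#", key, "="), "", line)
  }
  fs <- as.numeric(getmeta("sample_rate"))
  fb <- getmeta("feedback_channel")
  if (!nzchar(fb)) fb <- NULL
  long <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "hemisphere", "hbo", "hbr")
  unknown <- setdiff(names(long), need)
  if (length(unknown) > 0)
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  if (!all(need %in% names(long)))
    stop("missing columns: ", paste(setdiff(need, names(long)), collapse = ", "))
  chans <- unique(long$channel)
  nt <- nrow(long) / length(chans)
  if (nt != round(nt)) stop("unbalanced channel sample counts")
  hbo <- hbr <- matrix(NA_real_, nt, length(chans),
                       dimnames = list(NULL, chans))
  hemi <- character(length(chans))
  for (j in seq_along(chans)) {
    d <- long[long$channel == chans[j], ]
    if (is.unsorted(d$time_s, strictly = TRUE))
      stop("non-monotone or duplicate time for channel ", chans[j])
    hbo[, j] <- d$hbo
    hbr[, j] <- d$hbr
    hemi[j] <- d$hemisphere[1]
  }
  hb_recording(hbo, hbr, sample_rate = fs, channels = chans,
               hemisphere = hemi, feedback_channel = fb)
}

#' Write an event schedule to TSV
#' @param schedule An `event_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  validate_schedule(schedule)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#sample_rate=",
                    format(attr(schedule, "sample_rate"), digits = 15)), con)
  utils::write.table(as.data.frame(schedule)[, c("onset", "duration",
                                                 "condition", "run", "day",
                                                 "block", "trial")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event schedule from TSV
#' @param path File written by [write_events_tsv()].
#' @return An `event_schedule` data frame (validated).
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 2)
  fs <- 10
  m <- grep("^#sample_rate=", hdr, value = TRUE)
  if (length(m) == 1) fs <- as.numeric(sub("^#sample_rate=", "", m))
  ev <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL
  attr(ev, "sample_rate") <- fs
  class(ev) <- c("event_schedule", "data.frame")
  validate_schedule(ev)
  ev
}

#' Write / read behaviour trial tables
#' @param table A behaviour table (see [simulate_behavior()]).
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_behavior_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a session log as JSON
#'
#' Machine-readable provenance of a closed-loop session: per-trial
#' summaries, k history, final state, earnings, direction and the
#' parameters needed to re-execute the stage.
#'
#' @param session An `nf_session` from [run_closed_loop()].
#' @param path Output JSON path.
#' @param extra Named list of extra provenance fields (seeds, inputs).
#' @return `path`, invisibly.
#' @export
write_session_json <- function(session, path, extra = list()) {
  stopifnot(inherits(session, "nf_session"))
  payload <- c(list(
    direction = session$direction,
    md = session$md,
    trials = session$trials,
    k_history = session$k_history,
    final_state = unclass(session$state),
    total_earned = sum(session$trials$earned)
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
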