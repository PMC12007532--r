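# End-to-end convenience: simulate one participant's full training and
# push it through the closed loop and the success metrics.

#' Simulate and analyse one participant's full training
#'
#' Builds the default 12-run schedule, simulates a recording under the
#' given scenario, runs the closed-loop engine, and summarises runs and
#' participant-level success. The one-stop entry point for parameter-
#' recovery studies.
#'
#' @param direction `"up"` or `"down"`.
#' @param seed Integer seed driving schedule jitter and the recording
#'   noise (schedule and scenario seeds are derived from it).
#' @param scenario A [sim_scenario()], or `NULL` for the direction's
#'   default scenario.
#' @param config A [session_config()].
#' @param state Initial [threshold_state()].
#' @param keep_traces Keep per-sample traces (see [run_closed_loop()]).
#' @return A list with `schedule`, `sim` (recording + truth),
#'   `session` (`nf_session`), `runs` (per-run summaries) and
#'   `participant` (`participant_summary`).
#' @export
simulate_session <- function(direction = c("up", "down"), seed = 1L,
                             scenario = NULL,
                             config = session_config(direction = direction),
                             state = threshold_state(),
                             keep_traces = TRUE) {
  direction <- match.arg(direction)
  if (is.null(scenario))
    scenario <- sim_scenario(direction = direction, seed = seed + 1L)
  else if (is.null(scenario$seed)) scenario$seed <- seed + 1L
  schedule <- build_schedule(config, seed = seed)
  sim <- simulate_recording(schedule, scenario)
  session <- run_closed_loop(sim$recording, schedule, direction,
                             state = state, md = config$md,
                             keep_traces = keep_traces)
  runs <- summarize_runs(session$trials, direction)
  participant <- classify_participant(runs, direction,
                                      partial = nrow(runs) != 12)
  list(schedule = schedule, sim = sim, session = session,
       runs = runs, participant = participant)
}
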