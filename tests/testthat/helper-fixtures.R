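# Shared fixture builders. Everything is generated in code; no files.

# a small recording built directly from matrices
make_recording <- function(hbo, hbr = -0.5 * hbo, fs = 10,
                           hemisphere = NULL, feedback = NULL) {
  hbo <- as.matrix(hbo)
  hbr <- as.matrix(hbr)
  nch <- ncol(hbo)
  chans <- sprintf("C%02d", seq_len(nch))
  if (is.null(hemisphere))
    hemisphere <- rep(c("left", "right"), length.out = nch)
  if (is.null(feedback)) feedback <- chans[which(hemisphere == "right")[1]]
  hb_recording(hbo, hbr, sample_rate = fs, channels = chans,
               hemisphere = hemisphere, feedback_channel = feedback)
}

# a short training: `n_runs` runs of 6 blocks (default protocol timing)
mini_config <- function(n_runs = 1L, direction = "up") {
  session_config(direction = direction, runs_per_day = n_runs)
}

# noiseless scenario helper: everything off except what is requested
quiet_scenario <- function(direction = "up", n_runs = 1L,
                           amplitudes = rep(0, n_runs), ...) {
  sim_scenario(direction = direction, n_runs = n_runs,
               regulation_amplitudes = amplitudes,
               physio_amplitudes = c(cardiac = 0, respiration = 0, mayer = 0),
               drift_slope = 0, noise_sd = 0, dc_offset = 0,
               n_channels = 2, ...)
}
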