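test_that("coefficient of variation follows its definition", {
  set.seed(1)
  x <- stats::rnorm(1000, mean = 10, sd = 0.5)
  expect_equal(coefficient_of_variation(x),
               100 * stats::sd(x) / abs(mean(x)))
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(coefficient_of_variation(c(9, 10, 11)),
               100 * stats::sd(c(9, 10, 11)) / 10)
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))  # |mean| ~ 0
})

test_that("bad-channel screening applies the CoV, CoV-difference and flat-line rules", {
  set.seed(2)
  n <- 600
  base <- function(sd) 10 + stats::rnorm(n, sd = sd)
  hbo <- cbind(base(0.2), base(0.2), base(1.2), base(0.2), base(0.2),
               base(0.2))
  hbr <- cbind(base(0.2), base(0.2), base(0.2), base(0.2), base(0.2),
               base(0.2))
  hbo[101:112, 4] <- hbo[101, 4]          # 12 identical samples: flat
  hbo[201:209, 5] <- hbo[201, 5]          # 9 identical samples: below limit
  hbr[, 6] <- 10 + stats::rnorm(n, sd = 0.9)  # CoV diff > 5 points
  rec <- make_recording(hbo, hbr)
  rep_ <- detect_bad_channels(rec)
  ch <- rep_$channels
  expect_identical(ch$excluded, c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_true(ch$flatline_found[4])
  expect_false(ch$flatline_found[5])
  expect_match(ch$reason[3], "cov_hbo")
  expect_match(ch$reason[6], "cov_diff")
})

test_that("QC detector has full sensitivity and specificity on injected artifacts", {
  sched <- build_schedule(mini_config(1), seed = 3)
  sc <- sim_scenario("up", n_runs = 1, n_channels = 8, seed = 3,
                     artifacts = list(
                       list(channel = "L02", kind = "flatline",
                            onset = 60, duration = 3, magnitude = 0),
                       list(channel = "R03", kind = "high_variance",
                            onset = 0, duration = 360, magnitude = 5)))
  sim <- simulate_recording(sched, sc)
  ch <- detect_bad_channels(sim$recording)$channels
  expect_identical(ch$channel[ch$excluded], c("L02", "R03"))
})

test_that("re-inclusion requires a justification and is idempotent", {
  set.seed(4)
  hbo <- cbind(10 + stats::rnorm(300, sd = 2), 10 + stats::rnorm(300, sd = 0.1))
  rec <- make_recording(hbo, 10 + matrix(stats::rnorm(600, sd = 0.1), 300))
  rep_ <- detect_bad_channels(rec)
  expect_true(rep_$channels$excluded[1])
  expect_error(reinclude_channel(rep_, "C01", "  "), "justification")
  expect_error(reinclude_channel(rep_, "C02", "spikes removable"),
               "not excluded")
  rep2 <- reinclude_channel(rep_, "C01", "CoV driven by removable drift")
  expect_true(rep2$channels$reincluded[1])
  expect_true("C01" %in% good_channels(rep2))
  rep3 <- reinclude_channel(rep2, "C01", "again")
  expect_length(rep3$audit, 1)
})

test_that("bad trials are replaced by the mean of up to six neighbours", {
  trials <- lapply(c(1, 2, 3, 9, 4, 5, 6), function(v) rep(v, 20))
  # middle trial: neighbours 1,2,3 and 4,5,6 -> mean 3.5
  expect_equal(interpolate_bad_trials(trials, 4), rep(3.5, 20))
  # identical neighbours reproduce their value
  expect_equal(interpolate_bad_trials(rep(list(rep(2, 10)), 7), 4),
               rep(2, 10))
  # first trial: following three only
  expect_equal(interpolate_bad_trials(trials, 1), rep(mean(c(2, 3, 9)), 20))
  expect_error(interpolate_bad_trials(list(rep(1, 5)), 1), "no neighbouring")
})

test_that("outlier samples are replaced by the last retained observation", {
  x <- c(rep(0, 150), 100, rep(0, 149))
  r <- remove_outlier_samples(x)
  expect_equal(r$n_replaced, 1)
  expect_equal(r$series, rep(0, 300))

  clean <- sin(1:300)  # bounded well inside 3 sd
  expect_equal(remove_outlier_samples(clean)$n_replaced, 0)
  expect_identical(remove_outlier_samples(clean)$series, clean)

  y <- c(1, 2, 3, 500, 500, 2, 1, rep(c(1, 2, 3), 40))
  ry <- remove_outlier_samples(y)
  expect_equal(ry$series[4:5], c(3, 3))  # LOCF chain from last retained

  # replaced count is monotone in injected outliers
  base <- rep(0, 300)
  counts <- vapply(1:5, function(k) {
    z <- base; z[seq_len(k) * 40] <- 100
    remove_outlier_samples(z)$n_replaced
  }, 0L)
  expect_true(all(diff(counts) >= 0))

  # a leading outlier takes the next retained sample
  lead <- c(100, rep(0, 200))
  expect_equal(remove_outlier_samples(lead)$series[1], 0)
})

test_that("the stringent band-pass removes cardiac frequencies without lag", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  probe1 <- sin(2 * pi * 1 * t)
  out1 <- bandpass_001_009(probe1, fs)
  mid <- 2001:4000
  expect_lt(20 * log10(max(abs(out1[mid])) / 1), -20)

  probe_slow <- sin(2 * pi * 0.05 * t)
  out_slow <- bandpass_001_009(probe_slow, fs)
  expect_gt(max(abs(out_slow[mid])), 0.9)

  # DC removed (residual < 0.2% of the input level away from the edges)
  expect_lt(max(abs(bandpass_001_009(rep(5, 6001), fs)[mid])), 0.01)

  # zero phase: peak cross-correlation with the clean component at lag 0
  cc <- stats::ccf(out_slow[mid], probe_slow[mid], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("common average referencing cancels shared components and is linear", {
  n <- 200
  mk <- function(hbo) make_recording(hbo, -0.5 * hbo,
                                     hemisphere = rep(c("left", "right"),
                                                      each = ncol(hbo) / 2),
                                     feedback = sprintf("C%02d", ncol(hbo)))
  shared <- matrix(rep(sin(seq_len(n) / 5), 4), n)
  expect_equal(common_average_reference(mk(shared))$hbo, rep(0, n))

  hbo <- cbind(matrix(0, n, 2), matrix(stats::rnorm(2 * n), n))
  rec <- mk(hbo)
  expect_equal(common_average_reference(rec)$hbo, hbo[, 4])

  # 11 left channels at 1, 11 at 3, feedback constant 5 -> 5 - 2 = 3
  hbo2 <- cbind(matrix(1, n, 11), matrix(3, n, 11), matrix(5, n, 2))
  rec2 <- make_recording(hbo2, -0.5 * hbo2,
                         hemisphere = rep(c("left", "right"), c(22, 2)),
                         feedback = "C24")
  expect_equal(common_average_reference(rec2)$hbo, rep(3, n))

  # linearity: CAR(aX + bY) = a CAR(X) + b CAR(Y)
  set.seed(6)
  X <- matrix(stats::rnorm(4 * n), n)
  Y <- matrix(stats::rnorm(4 * n), n)
  a <- 2.5; b <- -1.3
  lhs <- common_average_reference(mk(a * X + b * Y))$hbo
  rhs <- a * common_average_reference(mk(X))$hbo +
    b * common_average_reference(mk(Y))$hbo
  expect_equal(lhs, rhs, tolerance = 1e-12)

  bad <- mk(shared)
  bad$channels$hemisphere[1] <- NA
  expect_error(common_average_reference(bad), "hemisphere")
})

test_that("offline replication reproduces the online trial summaries", {
  sched <- build_schedule(mini_config(1), seed = 11)
  sim <- simulate_recording(sched, sim_scenario("up", n_runs = 1,
                                                n_channels = 4, seed = 12))
  online <- run_closed_loop(sim$recording, sched, "up")
  off <- offline_reanalysis(sim$recording, sched, variant = "replication")
  expect_equal(off$median, online$trials$median, tolerance = 1e-6)
  expect_equal(off$sd, online$trials$sd, tolerance = 1e-6)
  expect_error(offline_reanalysis(sim$recording, sched, variant = "bogus"))
})

test_that("the band-pass re-analysis recovers clean trial medians under cardiac contamination", {
  sched <- build_schedule(mini_config(1), seed = 13)
  clean_sc <- quiet_scenario(n_runs = 1, amplitudes = 1, seed = 14)
  cardiac_sc <- quiet_scenario(n_runs = 1, amplitudes = 1, seed = 14)
  cardiac_sc$physio_amplitudes <- c(cardiac = 2, respiration = 0, mayer = 0)
  clean <- simulate_recording(sched, clean_sc)
  dirty <- simulate_recording(sched, cardiac_sc)
  ref <- offline_reanalysis(clean$recording, sched, variant = "robust1")
  rep_ <- offline_reanalysis(dirty$recording, sched, variant = "replication")
  rb1 <- offline_reanalysis(dirty$recording, sched, variant = "robust1")
  err_rep <- mean(abs(rep_$median - ref$median))
  err_rb1 <- mean(abs(rb1$median - ref$median))
  expect_lt(err_rb1, err_rep)
})

test_that("common average referencing cancels a montage-wide artifact", {
  sched <- build_schedule(mini_config(1), seed = 15)
  base_sc <- sim_scenario("up", n_runs = 1, n_channels = 8, seed = 16,
                          noise_sd = 0)
  glob_sc <- sim_scenario("up", n_runs = 1, n_channels = 8, seed = 16,
                          noise_sd = 0,
                          artifacts = list(list(channel = "all",
                                                kind = "spike", onset = 100,
                                                duration = 4, magnitude = 8)))
  base <- simulate_recording(sched, base_sc)
  glob <- simulate_recording(sched, glob_sc)
  ref <- offline_reanalysis(base$recording, sched, variant = "robust2")
  got <- offline_reanalysis(glob$recording, sched, variant = "robust2")
  expect_equal(got$median, ref$median, tolerance = 1e-6)
})
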