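# frequency response of a digital filter (b, a) at frequency f (Hz)
filter_gain <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(flt$b) - 1))
  zb <- sum(flt$b * z)
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(flt$a) - 1))
  Mod(zb / sum(flt$a * z))
}

# gain of a w-sample causal moving average
ma_gain <- function(w, f, fs) {
  if (f == 0) return(1)
  abs(sin(pi * f * w / fs) / (w * sin(pi * f / fs)))
}

test_that("device filter chain suppresses DC and high frequencies, passes the task band", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  as_rec <- function(x) make_recording(cbind(x, x), fs = fs)
  settled <- 3001:6000

  const <- device_preprocess(as_rec(rep(3.7, length(t))))
  expect_lt(max(abs(const$hbo[settled, 1])), 1e-6)

  hi <- device_preprocess(as_rec(sin(2 * pi * 2 * t)))
  expect_lt(max(abs(hi$hbo[settled, 1])), 0.10)

  # passband: compare to the designed composite response at 0.05 Hz
  pass <- device_preprocess(as_rec(sin(2 * pi * 0.05 * t)))
  hp <- signal::butter(2, 0.01 / (fs / 2), type = "high")
  lp <- signal::butter(2, 1 / (fs / 2), type = "low")
  g <- filter_gain(hp, 0.05, fs) * filter_gain(lp, 0.05, fs) *
    ma_gain(50, 0.05, fs)
  expect_equal(max(abs(pass$hbo[settled, 1])), g, tolerance = 0.05)

  expect_error(device_preprocess(make_recording(cbind(1:30, 1:30))),
               "shorter")
})

test_that("trial parameters reproduce the sd-ratio and window means", {
  p <- estimate_trial_params(c(0, 1, 2, 3), c(0, -0.5, -1, -1.5))
  expect_equal(p$alpha, 2)
  expect_equal(p$hbo_offset, 1.5)
  expect_equal(p$hbr_offset, -0.75)
  expect_false(p$degenerate)

  const <- estimate_trial_params(rep(5, 50), rep(5, 50))
  expect_true(const$degenerate)
  expect_equal(const$alpha, 1)
  expect_equal(const$hbo_offset, 5)
})

test_that("CBSI arithmetic matches its definition on random triples to machine precision", {
  expect_equal(cbsi_correct(1, -1, 1), 1)
  expect_equal(cbsi_correct(4, 0, 1), 2)
  expect_equal(cbsi_correct(0.6, -0.2, 1.5), 0.45)
  set.seed(1)
  x <- stats::rnorm(1e4); y <- stats::rnorm(1e4)
  a <- stats::runif(1e4, 0.1, 5)
  oracle <- vapply(seq_along(x), function(i) (x[i] - a[i] * y[i]) / 2, 0)
  expect_identical(cbsi_correct(x, y, a), oracle)
})

test_that("CBSI is exact when HbR mirrors HbO, and halves a shared motion spike", {
  # exact anticorrelation: output equals the HbO input
  x <- stats::rnorm(100)
  alpha <- 1.7
  expect_equal(cbsi_correct(x, -x / alpha, alpha), x, tolerance = 1e-14)

  # a spike moving HbO and HbR together is attenuated relative to raw HbO
  truth <- hrf(seq(0, 29.9, by = 0.1)) # clean response
  spike <- c(numeric(100), rep(5, 10), numeric(190))
  hbo <- truth + spike
  hbr <- -truth / 2 + spike
  corrected <- cbsi_correct(hbo, hbr, 2)
  expect_lt(max(abs(corrected - truth)), max(abs(hbo - truth)))
})

test_that("baseline normalisation centres and scales as specified", {
  r <- normalize_feedback(2, rep(1, 50))  # constant baseline, sd = 0
  expect_true(r$degenerate)
  expect_true(is.finite(r$signal))

  base <- rep(c(0.9, 1.0, 1.1), length.out = 50)
  r <- normalize_feedback(1.2, base)
  expect_equal(r$signal, (1.2 - stats::median(base)) / stats::sd(base))
  expect_false(r$degenerate)

  z <- normalize_feedback(stats::median(base), base)
  expect_equal(z$signal, 0)

  # unit baseline: median 0, sd 1
  set.seed(2)
  b <- stats::rnorm(50)
  b <- (b - stats::median(b)) / stats::sd(b)
  expect_equal(normalize_feedback(2, b)$signal, 2 / stats::sd(b),
               tolerance = 1e-12)
})

test_that("display smoothing ramps over 1 s without amplifying variation", {
  expect_equal(smooth_feedback(rep(4.2, 30)), rep(4.2, 30))

  step <- c(numeric(10), rep(10, 40))
  sm <- smooth_feedback(step)
  # not at target before one full ramp (1 s = 10 samples) has elapsed
  expect_lt(sm[19], 10)
  expect_true(all(diff(sm) >= 0))

  set.seed(3)
  for (i in 1:20) {
    x <- stats::rnorm(100)
    y <- smooth_feedback(x)
    expect_lte(sum(abs(diff(y))), sum(abs(diff(x))) + 1e-12)
  }
})

test_that("feedback mapping scales, flips, clamps and quantises as specified", {
  st <- threshold_state(T = 2, k = 0.25)
  expect_equal(map_feedback(2 * 0.25, st, "up")$feedback_value, 10)
  r0 <- map_feedback(0, st, "up")
  expect_equal(r0$feedback_value, 0)
  expect_false(r0$reward_on)
  r5 <- map_feedback(0.25, st, "up")
  expect_equal(r5$feedback_value, 5)
  expect_false(r5$reward_on)  # reward is strictly above level 5
  expect_true(map_feedback(0.26, st, "up")$reward_on)

  dn <- map_feedback(-0.1, threshold_state(T = 1, k = 0.25), "down")
  expect_equal(dn$feedback_value, 4)

  # clamping and the 11-image quantisation
  st1 <- threshold_state(T = 1, k = 0.25)
  sweep <- map_feedback(seq(-2, 2, by = 0.001), st1, "up")
  expect_true(all(sweep$feedback_value >= 0 & sweep$feedback_value <= 10))
  expect_identical(sort(unique(sweep$image_index)), 0:10)

  # affine below the clamp: map(a*s)/map(s) = a
  s <- 0.004; a <- 3
  m1 <- map_feedback(s, st1, "up")$feedback_value
  m2 <- map_feedback(a * s, st1, "up")$feedback_value
  expect_equal(m2 / m1, a, tolerance = 1e-12)
})

test_that("reward accrual pays 1 cent per second above level", {
  expect_equal(accrue_reward(rep(TRUE, 300)), 0.30)
  expect_equal(accrue_reward(rep(FALSE, 300)), 0)
  expect_equal(accrue_reward(rep(c(TRUE, FALSE), c(160, 140))), 0.16)
})

test_that("initial threshold follows the contrast-mean rule with fallbacks", {
  expect_equal(initial_threshold(2, 4), 3)
  expect_equal(initial_threshold(-3, 1), 1)   # negative mean, use positive
  expect_equal(initial_threshold(-1, -2), 1)  # both negative, default
  expect_equal(initial_threshold(-1, 5), 2)   # positive mean as printed
})

test_that("k adapts by 0.25 when time above level 5 reaches 75%", {
  st <- threshold_state(T = 1, k = 0.25)
  vals <- function(frac, n = 100) rep(c(6, 0), round(c(frac, 1 - frac) * n))
  expect_equal(adapt_k(vals(0.80), st)$k, 0.50)
  expect_equal(adapt_k(vals(0.74), st)$k, 0.25)
  expect_equal(adapt_k(vals(0.75), st)$k, 0.50)  # boundary inclusive
})

test_that("closed loop on a silent recording yields zero feedback and zero reward", {
  sched <- build_schedule(mini_config(1), seed = 5)
  sim <- simulate_recording(sched, quiet_scenario(n_runs = 1, seed = 5))
  ses <- run_closed_loop(sim$recording, sched, "up")
  expect_true(all(ses$trials$earned == 0))
  expect_true(all(vapply(ses$traces,
                         function(tr) all(tr$feedback_value == 0), TRUE)))
})

test_that("strong noiseless upregulation gives positive medians in every trial", {
  sched <- build_schedule(mini_config(1), seed = 6)
  sim <- simulate_recording(sched, quiet_scenario(n_runs = 1,
                                                  amplitudes = 2, seed = 6))
  ses <- run_closed_loop(sim$recording, sched, "up")
  expect_true(all(ses$trials$median > 0))
})

test_that("the down direction is the up mapping with the raw value negated", {
  sched <- build_schedule(mini_config(1), seed = 7)
  sc <- sim_scenario("up", n_runs = 1, n_channels = 2, seed = 8)
  sim <- simulate_recording(sched, sc)
  st <- threshold_state(T = 1e6)  # no adaptation interference
  up <- run_closed_loop(sim$recording, sched, "up", state = st)
  dn <- run_closed_loop(sim$recording, sched, "down", state = st)
  for (i in seq_along(up$traces)) {
    raw <- 10 * up$traces[[i]]$feedback_signal / (st$k * st$T)
    expect_equal(dn$traces[[i]]$feedback_value,
                 pmin(10, pmax(0, -raw)), tolerance = 1e-12)
  }
})

test_that("closed-loop replay is deterministic and respects reward bounds", {
  sched <- build_schedule(mini_config(2), seed = 9)
  sim <- simulate_recording(sched, sim_scenario("up", n_runs = 2,
                                                n_channels = 2, seed = 10))
  a <- run_closed_loop(sim$recording, sched, "up")
  b <- run_closed_loop(sim$recording, sched, "up")
  expect_identical(a$trials, b$trials)
  expect_true(all(a$trials$earned >= 0 & a$trials$earned <= 0.30))
  # full-training bound: 72 trials x 0.30 EUR
  expect_lte(sum(a$trials$earned) * 6, 21.60 + 1e-9)
})
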