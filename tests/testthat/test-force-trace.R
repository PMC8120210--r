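test_that("displacement converts linearly to force at the spring compliance", {
  expect_equal(displacement_to_force(0.71, 71)$force_mN, 10)
  expect_equal(displacement_to_force(0)$force_mN, 0)
  r <- displacement_to_force(-0.1, 71)
  expect_equal(r$force_mN, -1.408, tolerance = 1e-3)
  expect_true(r$compression)
  expect_error(displacement_to_force(Inf), "finite")
  expect_error(displacement_to_force(0.5, 0), "positive")
})

test_that("noiseless generator beats are recovered to within quantization", {
  ft <- generate_force_trace(trace_params(duration = 60, twitch_amplitude = 2,
                                          diastolic_force = 1, noise_sd = 0))
  b <- detect_beats(ft$trace)
  expect_equal(nrow(b), 60)
  expect_true(all(abs(b$amplitude_mN - 2) < 2e-3))
  expect_true(all(abs(b$diastolic_mN - 1) < 1e-6))
  # analytic peak time of the alpha pulse: r*log((r+d)/r)
  t_pk <- 0.05 * log((0.05 + 0.1) / 0.05)
  expect_true(all(abs(b$time_to_peak_s - t_pk) < 0.005))
  expect_true(all(b$captured))
})

test_that("a quiescent trace yields zero captured beats", {
  ft <- generate_force_trace(trace_params(duration = 20, twitch_amplitude = 0,
                                          noise_sd = 0.02, rng_seed = 7))
  b <- detect_beats(ft$trace)
  expect_equal(sum(b$captured), 0)
})

test_that("mean amplitude stays within 2% of truth under measurement noise", {
  ft <- generate_force_trace(trace_params(duration = 300, twitch_amplitude = 2,
                                          noise_sd = 0.05, rng_seed = 11))
  b <- detect_beats(ft$trace)
  expect_equal(mean(b$amplitude_mN), 2, tolerance = 0.02)
})

test_that("beat extrema agree with an exhaustive per-interval oracle", {
  ft <- generate_force_trace(trace_params(duration = 10, noise_sd = 0.03,
                                          rng_seed = 5))
  b <- detect_beats(ft$trace, smooth_n = 0)   # raw levels for exact agreement
  tr <- ft$trace
  for (k in seq_len(nrow(b))) {
    s <- b$beat_time_s[k]
    seg <- tr$force_mN[tr$time_s >= s & tr$time_s < s + 1]
    dw <- tr$force_mN[tr$time_s >= s + 0.8 & tr$time_s < s + 1]
    expect_equal(b$peak_mN[k], max(seg))
    expect_equal(b$diastolic_mN[k], min(dw))
  }
})

test_that("force scaling scales force outputs and leaves time outputs unchanged", {
  ft <- generate_force_trace(trace_params(duration = 20, noise_sd = 0.02,
                                          rng_seed = 3))
  b1 <- detect_beats(ft$trace)
  tr2 <- ft$trace
  tr2$force_mN <- tr2$force_mN * 3.7
  b2 <- detect_beats(tr2)
  expect_equal(b2$amplitude_mN, b1$amplitude_mN * 3.7, tolerance = 1e-12)
  expect_equal(b2$diastolic_mN, b1$diastolic_mN * 3.7, tolerance = 1e-12)
  expect_equal(b2$time_to_peak_s, b1$time_to_peak_s)
  expect_equal(b2$contraction_duration_s, b1$contraction_duration_s)
  expect_equal(b2$relaxation_rate_per_s, b1$relaxation_rate_per_s,
               tolerance = 1e-12)
})

test_that("conditioning bins average beats and exclude zero-force gaps", {
  # constant-amplitude day: every bin equals the constant
  beats <- data.frame(beat = 1:600, beat_time_s = 0:599,
                      diastolic_mN = 1, peak_mN = 3, amplitude_mN = 2,
                      time_to_peak_s = 0.05, relaxation_rate_per_s = 10,
                      contraction_duration_s = 0.2, captured = TRUE)
  attr(beats, "pacing_interval") <- 1
  tc <- conditioning_timecourse(beats, bin_s = 60)
  expect_true(all(tc$mean_twitch_mN == 2))
  # a 2-min non-captured run is treated as a gap and excluded
  beats2 <- beats
  beats2$captured[200:319] <- FALSE
  beats2$amplitude_mN[200:319] <- 0
  tc2 <- conditioning_timecourse(beats2, bin_s = 60, gap_min_s = 100)
  expect_true(all(tc2$mean_twitch_mN[!is.na(tc2$mean_twitch_mN)] == 2))
  expect_equal(sum(tc2$n_beats), 480)
})

test_that("baseline drift appears in the diastolic time course at the set rate", {
  ft <- generate_force_trace(trace_params(duration = 1000, drift_rate = 3.6,
                                          noise_sd = 0))
  tc <- conditioning_timecourse(detect_beats(ft$trace), bin_s = 100)
  rise <- tc$mean_diastolic_mN[nrow(tc)] - tc$mean_diastolic_mN[1]
  expect_equal(rise, 3.6 / 3600 * 900, tolerance = 0.02)
})

test_that("stretch-step response recovers gains and diastolic jump", {
  p <- trace_params(duration = 200, stretch_events = list(
    list(time = 100, step_gain = 1.3, diastolic_jump = 0.2,
         relaxation_tau = 300)))
  b <- detect_beats(generate_force_trace(p)$trace)
  r <- stretch_step_response(b, 100, window_s = 20, persist_at_s = 60)
  expect_equal(r$acute_gain, 1.3, tolerance = 0.01)
  # the jump itself relaxes slightly over the post window
  expect_equal(r$diastolic_jump_mN, 0.2, tolerance = 0.03)
  # persistence between baseline and acute gain, near the generator model
  g_model <- 1 + 0.3 * (0.5 + 0.5 * exp(-70 / 300))
  expect_gt(r$persistent_gain_24h, 1)
  expect_lt(r$persistent_gain_24h, r$acute_gain)
  expect_equal(r$persistent_gain_24h, g_model, tolerance = 0.02)
  # identity event
  p0 <- trace_params(duration = 200, stretch_events = list(
    list(time = 100, step_gain = 1, diastolic_jump = 0, relaxation_tau = 300)))
  b0 <- detect_beats(generate_force_trace(p0)$trace)
  r0 <- stretch_step_response(b0, 100, window_s = 20, persist_at_s = 60)
  expect_equal(r0$acute_gain, 1, tolerance = 1e-6)
  expect_equal(r0$diastolic_jump_mN, 0, tolerance = 1e-6)
  expect_error(stretch_step_response(b, 100, window_s = 20,
                                     persist_at_s = 86400),
               "persistence window")
})

test_that("hypoxia residual is 100% without decline and errors past trace end", {
  ft <- generate_force_trace(trace_params(duration = 480, noise_sd = 0))
  b <- detect_beats(ft$trace)
  expect_equal(hypoxia_residual(b, 300, 120), 100, tolerance = 0.01)
  expect_error(hypoxia_residual(b, 450, 120), "past the last")
})

test_that("stimulation threshold handles monotone and ambiguous capture tables", {
  expect_equal(stimulation_threshold(c(5, 10, 15, 20), c(F, F, T, T)), 15)
  expect_error(stimulation_threshold(50, TRUE), "outside tested range")
  expect_warning(th <- stimulation_threshold(c(5, 10, 15, 20), c(F, T, F, T)),
                 "non-monotone")
  expect_equal(th, 12.5)
})
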