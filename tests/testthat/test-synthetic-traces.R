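test_that("noiseless twitch train has one pulse per pacing interval at the set amplitude", {
  ft <- generate_force_trace(trace_params(duration = 60, pacing_rate = 1,
                                          twitch_amplitude = 2, noise_sd = 0,
                                          drift_rate = 0))
  tr <- ft$trace
  expect_length(attr(tr, "stim_times"), 60)
  peaks <- vapply(0:59, function(k) {
    seg <- tr$force_mN[tr$time_s >= k & tr$time_s < k + 1]
    max(seg) - min(seg)
  }, 0)
  # peak sample sits within one sampling interval of the true maximum
  expect_true(all(abs(peaks - 2) < 1e-3))
})

test_that("identical seeds give bitwise-identical traces, different seeds differ", {
  p <- trace_params(duration = 5, noise_sd = 0.1, rng_seed = 42L)
  a <- generate_force_trace(p)
  b <- generate_force_trace(p)
  expect_identical(a$trace$force_mN, b$trace$force_mN)
  p2 <- trace_params(duration = 5, noise_sd = 0.1, rng_seed = 43L)
  expect_false(identical(generate_force_trace(p2)$trace$force_mN,
                         a$trace$force_mN))
})

test_that("hypoxia ground truth records the end-of-window residual", {
  tau <- hypoxia_tau_for_residual(0.64)
  ft <- generate_force_trace(trace_params(
    duration = 480, noise_sd = 0,
    hypoxia_window = list(start = 300, duration = 120, decline_tau = tau)))
  res <- ft$truth$value[ft$truth$parameter == "residual_pct"]
  expect_equal(res, 64, tolerance = 1e-9)
})

test_that("a pacing interval shorter than the pulse support is rejected", {
  expect_error(
    generate_force_trace(trace_params(pacing_rate = 4, rise_tau = 0.05,
                                      decay_tau = 0.1, duration = 5)),
    "pulse support")
})

test_that("calcium transient peaks at F0*(1+a) and decays log-linearly at -1/tau", {
  ca <- generate_ca_transient(amplitude = 1.5, tau = 0.3, f0 = 100,
                              noise_sd = 0)
  expect_equal(max(ca$trace$intensity), 250, tolerance = 1e-6)
  # log-linear slope of the decay segment of the first transient
  tr <- ca$trace
  dec <- tr[tr$time_s > 0.06 & tr$time_s < 1.2, ]
  slope <- unname(coef(lm(log(dec$intensity - 100) ~ dec$time_s))[2])
  expect_equal(slope, -1 / 0.3, tolerance = 1e-6)
})

test_that("seeded noisy calcium traces are reproducible and keep exact truth", {
  a <- generate_ca_transient(tau = 0.27, noise_sd = 2, rng_seed = 9L)
  b <- generate_ca_transient(tau = 0.27, noise_sd = 2, rng_seed = 9L)
  expect_identical(a$trace$intensity, b$trace$intensity)
  expect_equal(a$truth$value[a$truth$parameter == "tau"], 0.27)
})

test_that("action-potential construction honours peak, upstroke time and resting floor", {
  ap <- generate_action_potential(rmp = -72.4, amplitude = 99.7,
                                  upstroke_velocity = 13.47, apd90 = 0.35,
                                  duration = 2, noise_sd = 0)
  v <- ap$trace$voltage_mV
  expect_equal(max(v), -72.4 + 99.7, tolerance = 0.05)
  expect_equal(min(v), -72.4, tolerance = 1e-9)
  # 10 V/s upstroke over 100 mV lasts exactly 10 ms
  ap2 <- generate_action_potential(rmp = -70, amplitude = 100,
                                   upstroke_velocity = 10, apd90 = 0.3,
                                   duration = 2, noise_sd = 0)
  t_peak <- ap2$trace$time_s[which.max(ap2$trace$voltage_mV[ap2$trace$time_s < 1])]
  expect_equal(t_peak, 0.010, tolerance = 3e-4)
})

test_that("an apd90 that does not fit the pacing interval is rejected", {
  expect_error(generate_action_potential(apd90 = 1.2, pacing_rate = 1),
               "pacing interval")
  expect_error(generate_action_potential(apd90 = 0.9, pacing_rate = 1),
               "repolarization")
})
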