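test_that("frank_starling finds the optimum preload and systolic/diastolic ratio", {
  cv <- length_force_curve(length_mm = c(10, 14, 18),
                           diastolic_mN = c(0.2, 0.5, 1.5),
                           twitch_mN = c(1, 3, 2), slack_length_mm = 10)
  fs <- frank_starling(cv)
  expect_equal(fs$optimum_relative_length, 1.4)
  expect_equal(fs$max_twitch_mN, 3)
  # constructed optimum-preload forces: systolic 11.37, diastolic 1.20
  cv2 <- length_force_curve(length_mm = c(10, 12, 14, 16, 18),
                            diastolic_mN = c(0.15, 0.35, 0.7, 1.20, 2.4),
                            twitch_mN = c(2, 5, 8, 10.17, 9.5),
                            slack_length_mm = 10)
  fs2 <- frank_starling(cv2)
  expect_equal(fs2$sys_dia_ratio, 11.37 / 1.20, tolerance = 1e-12)
  # near-zero diastolic force gives an undefined ratio, not infinity
  cv3 <- length_force_curve(length_mm = c(10, 12, 14),
                            diastolic_mN = c(0, 0, 0),
                            twitch_mN = c(1, 3, 2), slack_length_mm = 10)
  expect_warning(fs3 <- frank_starling(cv3), "undefined")
  expect_true(is.na(fs3$sys_dia_ratio))
  expect_error(frank_starling(cv[1:2, ]), "3 length steps")
})

test_that("elastic modulus equals the stress-strain slope and scales linearly", {
  geo <- tissue_geometry(slack_length_mm = 10, actinin_cross_section_mm2 = 1)
  cv <- length_force_curve(length_mm = c(10, 12, 14),
                           diastolic_mN = c(0, 0.9, 1.8),
                           twitch_mN = c(1, 2, 3), slack_length_mm = 10)
  em <- elastic_modulus(cv, geo)
  expect_equal(em$modulus_kPa, 4.5, tolerance = 1e-12)
  cv2 <- cv
  cv2$diastolic_mN <- cv2$diastolic_mN * 2
  cv2$systolic_mN <- cv2$diastolic_mN + cv2$twitch_mN
  expect_equal(elastic_modulus(cv2, geo)$modulus_kPa, 9, tolerance = 1e-12)
})

test_that("modulus matches the closed-form least-squares oracle on nonlinear data", {
  set.seed(1)
  strain <- c(0, 0.1, 0.2, 0.3, 0.4)
  stress <- 2 * strain + 5 * strain^2
  geo <- tissue_geometry(actinin_cross_section_mm2 = 1)
  cv <- length_force_curve(length_mm = 10 * (1 + strain),
                           diastolic_mN = stress,
                           twitch_mN = rep(1, 5), slack_length_mm = 10)
  em <- elastic_modulus(cv, geo, window = "all")
  slope_oracle <- sum((strain - mean(strain)) * (stress - mean(stress))) /
    sum((strain - mean(strain))^2)
  expect_equal(em$modulus_kPa, slope_oracle, tolerance = 1e-12)
})

test_that("specific force is the twitch per actinin cross-section with units", {
  sf <- specific_force(2.82, tissue_geometry(actinin_cross_section_mm2 = 0.25))
  expect_equal(as.numeric(sf), 11.28, tolerance = 1e-12)
  expect_equal(attr(sf, "units"), "mN/mm^2")
  expect_equal(as.numeric(specific_force(0, 0.25)), 0)
  expect_error(specific_force(1, 0), "positive")
})

test_that("ffr normalizes by 1 Hz and classifies the slope sign", {
  pos <- ffr(c(`1` = 2.0, `2` = 2.3, `3` = 2.5, `4` = 2.4))
  expect_equal(pos$peak_fold, 1.25, tolerance = 1e-12)
  expect_equal(pos$peak_rate_Hz, 3)
  expect_equal(pos$classification, "positive")
  neg <- ffr(c(`1` = 2.0, `2` = 1.8, `3` = 1.5))
  expect_equal(neg$classification, "negative")
  flat <- ffr(c(`1` = 2, `2` = 2, `3` = 2))
  expect_equal(flat$classification, "flat")
  expect_equal(flat$peak_fold, 1)
  expect_error(ffr(c(`2` = 2, `3` = 2.5)), "1 Hz")
})

test_that("drug response reports per-metric fold changes over pre-treatment", {
  p <- trace_params(duration = 40, noise_sd = 0)
  b <- detect_beats(generate_force_trace(p)$trace)
  same <- drug_response(b, b)
  expect_equal(same$twitch_fold, 1)
  expect_equal(same$relaxation_rate_fold, 1)
  expect_equal(same$contraction_duration_fold, 1)
  b2 <- b
  b2$amplitude_mN <- b2$amplitude_mN * 1.5
  expect_equal(drug_response(b, b2)$twitch_fold, 1.5, tolerance = 1e-12)
  # faster relaxation (shorter decay tau) shortens contraction duration
  p_fast <- trace_params(duration = 40, decay_tau = 0.06, noise_sd = 0)
  b_fast <- detect_beats(generate_force_trace(p_fast)$trace)
  r <- drug_response(b, b_fast)
  expect_lt(r$contraction_duration_fold, 1)
  expect_gt(r$relaxation_rate_fold, 1)
})

test_that("ratio metrics are invariant to a common force rescaling", {
  cv <- length_force_curve(length_mm = c(10, 12, 14, 16, 18),
                           diastolic_mN = c(0.15, 0.35, 0.7, 1.2, 2.4),
                           twitch_mN = c(2, 5, 8, 10.17, 9.5),
                           slack_length_mm = 10)
  geo <- tissue_geometry(actinin_cross_section_mm2 = 0.25)
  for (c_scale in c(0.5, 3)) {
    cv2 <- length_force_curve(cv$length_mm, cv$diastolic_mN * c_scale,
                              cv$twitch_mN * c_scale, 10)
    expect_equal(frank_starling(cv2)$sys_dia_ratio,
                 frank_starling(cv)$sys_dia_ratio, tolerance = 1e-12)
    expect_equal(elastic_modulus(cv2, geo)$modulus_kPa,
                 elastic_modulus(cv, geo)$modulus_kPa * c_scale,
                 tolerance = 1e-12)
    f <- c(`1` = 2.0, `2` = 2.3, `3` = 2.5)
    expect_equal(ffr(f * c_scale)$peak_fold, ffr(f)$peak_fold,
                 tolerance = 1e-12)
  }
})
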