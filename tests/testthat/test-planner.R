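model_nx <- drug_model("iv_naloxone")

test_that("full-blockade windows reproduce the published durations", {
  w_high <- full_blockade_window(model_nx, 0.10)
  expect_true(w_high$attained)
  # published "~65 min" at 0.10-0.15 mg/kg; the full-precision chain gives ~67
  expect_equal(w_high$duration, 65, tolerance = 10 / 65)
  expect_equal(round(w_high$duration / 5) * 5, 65)

  w_low <- full_blockade_window(model_nx, 0.01)
  expect_equal(w_low$duration, 30, tolerance = 7 / 30)
  expect_equal(w_low$onset, 15, tolerance = 2 / 15) # "minimum 15 min" delay
  expect_lt(w_high$onset, w_low$onset)

  td <- tidy(w_low)
  expect_equal(td$duration, w_low$offset - w_low$onset)
})

test_that("windows handle unattained thresholds and respond monotonically", {
  none <- full_blockade_window(model_nx, 0.0005)
  expect_false(none$attained)
  expect_equal(none$duration, 0)
  expect_true(is.na(none$onset))

  # duration grows with dose, shrinks with threshold
  doses <- c(0.01, 0.03, 0.1, 0.3)
  durs <- vapply(doses, function(d) full_blockade_window(model_nx, d)$duration, 1.0)
  expect_true(all(diff(durs) > 0))
  thr <- c(50, 70, 90, 95)
  durs_t <- vapply(thr, function(th) {
    full_blockade_window(model_nx, 0.1, threshold = th)$duration
  }, 1.0)
  expect_true(all(diff(durs_t) < 0))
})

test_that("washout times follow the five-half-life rule", {
  expect_equal(washout_time(72 * 60, 5), 360 * 60) # 15 days in minutes
  expect_equal(washout_time(72 * 60, 5) / 1440, 15)
  expect_equal(washout_time(110, 5), 550) # ~9.2 h
  expect_equal(washout_time(110, 5) / 60, 9.2, tolerance = 0.01)
  # linear in both arguments
  expect_equal(washout_time(110, 10), 2 * washout_time(110, 5))
  expect_equal(washout_time(220, 5), 2 * washout_time(110, 5))
  expect_error(washout_time(0), class = "opioidblockr_domain_error")
})

test_that("minimum dose inverts the simulation chain", {
  # at the measurement time with no absorption the chain collapses to Eq-1
  d50 <- min_dose_for(model_nx, target_blockade = 50, at_time = 55,
                      absorption = FALSE)
  expect_equal(d50, model_nx$fit$ed50, tolerance = 1e-10)

  d90 <- min_dose_for(model_nx, target_blockade = 90, at_time = 30)
  expect_gt(d90, 0.005)
  expect_lt(d90, 0.01)
  # forward simulation reproduces the target at at_time
  cv <- blockade_time_curves(model_nx, d90, receptors = "MOR",
                             times = c(29, 30, 31), truncate = FALSE)
  expect_equal(cv$value[cv$time == 30], 90, tolerance = 1e-6)
  # and the window contains at_time
  w <- full_blockade_window(model_nx, d90)
  expect_lte(w$onset, 30)
  expect_gte(w$offset, 30)

  expect_error(min_dose_for(model_nx, target_blockade = 100, at_time = 30),
               class = "opioidblockr_unattainable")
  # beyond the reach of any single bolus (profile shape bound)
  expect_error(min_dose_for(model_nx, target_blockade = 90, at_time = 180),
               class = "opioidblockr_unattainable")
})

test_that("cost estimates use whole purchasable units", {
  ce <- cost_estimate("iv_naloxone", dose = 0.1, weight_kg = 70)
  expect_equal(ce$total_drug, 7)
  expect_equal(ce$units_needed, 18) # ceiling(7 / 0.4)
  expect_equal(ce$cost_range, 18 * c(4.58, 7.07))
  expect_equal(ce$cost_mid, 105, tolerance = 0.01)

  ct <- cost_estimate("oral_naltrexone", dose = 50)
  expect_equal(ct$units_needed, 1)
  expect_equal(ct$cost_range, c(4.28, 9.72))

  # exact division needs no extra unit
  ce2 <- cost_estimate("iv_naloxone", dose = 0.2, weight_kg = 10) # 2 mg
  expect_equal(ce2$units_needed, 5)
  # minimal covering integer
  expect_gte(ce$units_needed * 0.4, ce$total_drug)
  expect_lt((ce$units_needed - 1) * 0.4, ce$total_drug)

  expect_error(cost_estimate("iv_naloxone", dose = 0.1),
               class = "opioidblockr_missing_parameter")
})

test_that("bolus-plus-infusion regimens hold the threshold and save drug", {
  # a hold within the bolus's own window needs no infusion
  r_short <- regimen_hold(model_nx, hold_until = 30)
  expect_equal(r_short$infusion_amplitude, 0)
  expect_equal(nrow(r_short$events), 1L)

  r_long <- regimen_hold(model_nx, hold_until = 180)
  expect_gt(r_long$infusion_amplitude, 0)
  # self-check: forward simulation stays above threshold over the hold
  prof <- pk_profile(r_long$events, k = model_nx$kinetics$k_per_min,
                     ka = model_nx$kinetics$ka_per_min,
                     times = seq(15, 180, 0.5), truncate = FALSE)
  expect_true(all(prof$value >= 90 - 1e-6))
  # no single bolus can hold 90% that long, yet the regimen is finite
  expect_error(min_dose_for(model_nx, target_blockade = 90, at_time = 180),
               class = "opioidblockr_unattainable")

  # where a single bolus can reach, the combined regimen uses less drug
  r70 <- regimen_hold(model_nx, hold_until = 70)
  single70 <- min_dose_for(model_nx, target_blockade = 90, at_time = 70)
  expect_lt(r70$total_dose_equivalent, single70)
})
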