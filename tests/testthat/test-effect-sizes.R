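# Frozen reference values below were computed with an independent
# arbitrary-precision evaluation (40 significant digits) of the same
# formulas.

test_that("activation energy matches the hand-computed reference contrast", {
  # V_o = 10, V_i = 8 at 300 K -> 302 K
  rec <- experiment_records(make_record(
    control_mean = 10, treatment_mean = 8,
    t_control_C = 300 - 273.15, t_treatment_C = 302 - 273.15))
  eff <- activation_energy(rec)
  expect_equal(eff$delta_inv_kT, 0.2561802853387254, tolerance = 1e-12)
  expect_equal(eff$value, 0.8710410756985691, tolerance = 1e-12)
  # delta-method variance: SD = 1, n = 4, mean 10 / 8
  v_ln <- 1 / (4 * 100) + 1 / (4 * 64)
  expect_equal(eff$variance, v_ln / 0.2561802853387254^2, tolerance = 1e-12)
})

test_that("equal rates give E = 0 and label swap leaves E unchanged", {
  rec <- experiment_records(make_record(treatment_mean = 10))
  expect_equal(activation_energy(rec)$value, 0)

  a <- make_record(control_mean = 10, treatment_mean = 7,
                   t_control_C = 26, t_treatment_C = 29)
  # swapping arm labels negates both the log ratio and delta(1/kT)
  b <- make_record(control_mean = 7, treatment_mean = 10,
                   t_control_C = 29, t_treatment_C = 26)
  ea <- activation_energy(as.data.frame(experiment_records(a)))
  eb <- suppressWarnings(activation_energy(b))
  expect_equal(ea$value, eb$value, tolerance = 1e-12)
})

test_that("E is strictly decreasing in the treatment mean", {
  vi <- seq(5, 15, by = 0.5)
  vals <- vapply(vi, function(v) {
    activation_energy(make_record(treatment_mean = v))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("CO2 log response ratio matches the reference and its scaling laws", {
  rec <- experiment_records(make_record(
    arm_type = "co2", control_mean = 10, treatment_mean = 9,
    t_treatment_C = 26.85, pco2_control_uatm = 400,
    pco2_treatment_uatm = 800))
  eff <- lnrr_co2(rec)
  expect_equal(eff$value, -0.026340128914456575, tolerance = 1e-12)
  expect_equal(eff$delta_pco2_uatm, 400)

  # equal means -> 0
  eq <- make_record(arm_type = "co2", treatment_mean = 10,
                    t_treatment_C = 26.85, pco2_treatment_uatm = 800)
  expect_equal(lnrr_co2(eq)$value, 0)

  # doubling the pCO2 difference halves the value; variance scales by 1/4
  wide <- make_record(arm_type = "co2", treatment_mean = 9,
                      t_treatment_C = 26.85, pco2_treatment_uatm = 1200)
  expect_equal(lnrr_co2(wide)$value, eff$value / 2, tolerance = 1e-12)
  expect_equal(lnrr_co2(wide)$variance, eff$variance / 4, tolerance = 1e-12)

  # invariant under common rescaling of both means (SDs rescaled too)
  scaled <- make_record(arm_type = "co2", control_mean = 1000,
                        treatment_mean = 900, control_sd = 100,
                        treatment_sd = 100, t_treatment_C = 26.85,
                        pco2_treatment_uatm = 800)
  es <- lnrr_co2(scaled)
  expect_equal(es$value, eff$value, tolerance = 1e-12)
  expect_equal(es$variance, eff$variance, tolerance = 1e-12)
})

test_that("delta-method variance matches the worked example and floors at zero SD", {
  rec <- make_record()  # SD 1, n 4, means 10 and 8
  rec$treatment_mean <- 10
  expect_equal(effect_variance(rec, "arrhenius_E"),
               0.005 / 0.2561802853387254^2, tolerance = 1e-10)
  expect_equal(0.005 / 0.2561802853387254^2, 0.076186600285005,
               tolerance = 1e-12)

  degenerate <- make_record(control_sd = 0, treatment_sd = 0)
  expect_warning(v <- effect_variance(degenerate, "arrhenius_E",
                                      variance_floor = 1e-8),
                 "variance floor")
  expect_equal(v, 1e-8)

  small_n <- make_record(control_n = 1)
  expect_error(effect_variance(small_n, "arrhenius_E"), "n >= 2")
})

test_that("degenerate contrasts and wrong arm types are rejected", {
  same_T <- make_record(t_treatment_C = 26.85)
  expect_error(activation_energy(same_T), "degenerate")
  expect_error(activation_energy(make_record(arm_type = "co2")), "arm_type")
  expect_error(lnrr_co2(make_record(arm_type = "warming")), "arm_type")
  same_p <- make_record(arm_type = "co2", t_treatment_C = 26.85)
  expect_error(lnrr_co2(same_p), "degenerate")
})

test_that("effect_sizes splits records by kind and labels co-stressor context", {
  df <- rbind(make_record(study_id = "w", arm_type = "warming"),
              make_record(study_id = "c", arm_type = "co2",
                          t_treatment_C = 26.85, pco2_treatment_uatm = 800),
              make_record(study_id = "b", arm_type = "both",
                          pco2_treatment_uatm = 800))
  eff <- effect_sizes(experiment_records(df))
  # 'both' records contribute to both kinds
  expect_equal(sum(eff$kind == "arrhenius_E"), 2)
  expect_equal(sum(eff$kind == "lnrr_co2"), 2)
  expect_setequal(eff$context[eff$study_id == "b"], "under_co_stressor")
  expect_setequal(eff$context[eff$study_id != "b"], "single_driver")
})

test_that("continuity correction substitutes 0.5/n for zero survival means", {
  rec <- make_record(treatment_mean = 0)
  expect_error(activation_energy(rec), "positive means")
  expect_message(eff <- activation_energy(rec, continuity = TRUE),
                 "continuity")
  expect_equal(eff$value,
               log(10 / (0.5 / 4)) / 0.2561802853387254, tolerance = 1e-10)
})
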