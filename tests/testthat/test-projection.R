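test_that("the analytic map matches the hand-computed 1 degree increment at 27 C", {
  m <- fit_arrhenius_map(baseline_temperature_C = 27)
  expect_equal(predict(m, 1), 0.1283874851090063, tolerance = 1e-10)
  expect_equal(predict(m, 0), 0)
})

test_that("a fitted map recovers a linear relation exactly and tracks the analytic curve", {
  # records generated from an exactly linear map: OLS recovers it
  dT <- seq(0.5, 5, by = 0.5)
  d <- 0.01 + 0.128 * dT
  ols <- lm(d ~ dT)
  expect_equal(unname(coef(ols)), c(0.01, 0.128), tolerance = 1e-10)

  # records all with controls at 27 C: fitted map tracks the analytic map
  # within the curvature of 1/(kT) over [0, 5] degrees
  rec <- do.call(rbind, lapply(dT, function(x) {
    make_record(t_control_C = 27, t_treatment_C = 27 + x)
  }))
  fitted_map <- fit_arrhenius_map(experiment_records(rec))
  analytic <- fit_arrhenius_map(baseline_temperature_C = 27)
  grid <- seq(0, 5, by = 0.25)
  expect_lt(max(abs(predict(fitted_map, grid) - predict(analytic, grid))),
            5e-3)

  # identical increments leave the linear map singular
  same <- do.call(rbind, lapply(1:3, function(i) {
    make_record(study_id = paste0("s", i))
  }))
  expect_error(fit_arrhenius_map(experiment_records(same)), "singular")
})

test_that("warming back-transformation reproduces the reference declines", {
  # pooled survival E = 0.7 eV at the late-century RCP8.5 intensity
  p1 <- percent_change_temp(c(0.7, 0), delta_T = 4.32)
  expect_equal(p1$percent_change, -31.887556778551557, tolerance = 1e-10)
  p2 <- percent_change_temp(c(0.7, 0), delta_T = 0.97)
  expect_equal(p2$percent_change, -8.349136265484755, tolerance = 1e-10)
  # E = 0 -> no change at any warming
  p0 <- percent_change_temp(c(0, 0), delta_T = c(0, 1, 5))
  expect_equal(p0$percent_change, c(0, 0, 0))
})

test_that("CO2 back-transformation reproduces the reference decline and e-scaling", {
  p <- percent_change_co2(c(-0.0197, 0), delta_pco2 = 490)
  expect_equal(p$percent_change, -9.201734228857779, tolerance = 1e-10)
  expect_equal(percent_change_co2(c(0, 0), delta_pco2 = 490)$percent_change, 0)
  # change(63) = 100*((1 + change(100)/100)^0.63 - 1) for any lnrr
  lnrr <- -0.0321
  c100 <- percent_change_co2(c(lnrr, 0), 100)$percent_change
  c63 <- percent_change_co2(c(lnrr, 0), 63)$percent_change
  expect_equal(c63, 100 * ((1 + c100 / 100)^0.63 - 1), tolerance = 1e-10)
})

test_that("effect size and back-transformation are exact inverses on noiseless records", {
  for (decline in c(5, 20, 60)) {
    for (dT in c(0.5, 2, 4.32)) {
      rec <- make_record(control_mean = 10,
                         treatment_mean = 10 * (1 - decline / 100),
                         t_control_C = 27, t_treatment_C = 27 + dT)
      E <- activation_energy(rec)$value
      back <- percent_change_temp(c(E, 0), delta_T = dT,
                                  map = fit_arrhenius_map(
                                    baseline_temperature_C = 27))
      expect_equal(back$percent_change, -decline, tolerance = 1e-10)
    }
  }
})

test_that("percent decline grows monotonically with warming and is bounded by 100", {
  pc <- percent_change_temp(c(0.7, 0), delta_T = seq(0, 13, by = 0.5))
  expect_true(all(diff(pc$percent_change) < 0))
  expect_true(all(pc$percent_change > -100))
  # CI order is preserved by the monotone back-transform
  pc2 <- percent_change_temp(c(0.7, 0.2), delta_T = 3)
  expect_lte(pc2$ci_low, pc2$percent_change)
  expect_gte(pc2$ci_high, pc2$percent_change)
})

test_that("kind mismatches between fit and transform are type errors", {
  eff <- data.frame(value = c(0.6, 0.8), variance = c(0.01, 0.01),
                    study_id = c("a", "b"), genus = c("g1", "g2"),
                    kind = "arrhenius_E", attribute = "survival",
                    context = "single_driver")
  f <- coral_meta(eff)
  expect_error(percent_change_co2(f, 100), "kind")
  proj <- predict(f, delta_T = 2)
  expect_s3_class(proj, "coral_projection")
  expect_error(predict(f), "delta_T or delta_pco2")
})

test_that("minimum significant increment follows the precision rule", {
  # CI strictly excluding zero: first scanned step is already significant
  tight <- min_significant_delta(c(0.7, 0.1), "temperature", step = 0.01,
                                 cap = 13)
  expect_equal(tight$min_delta, 0.01)
  # CI including zero: no increment can become significant
  loose <- min_significant_delta(c(0.1, 0.2), "temperature", step = 0.5,
                                 cap = 5)
  expect_true(is.na(loose$min_delta))
  # rounded reporting rule: threshold appears once the weaker CI bound
  # grows past 0.5% in magnitude (regression value from a direct scan)
  se <- (0.7 - 0.02) / 1.96
  r <- min_significant_delta(c(0.7, se), "temperature",
                             precision_rule = "rounded", digits = 0)
  expect_equal(r$min_delta, 1.96, tolerance = 1e-9)
  expect_gt(r$min_delta, 0.01)
  expect_equal(r$percent_change_at_min, -16.10363, tolerance = 1e-4)
})

test_that("project_all crosses fits with scenarios and reports gaps", {
  effE <- data.frame(value = c(0.6, 0.8), variance = 0.01,
                     study_id = c("a", "b"), genus = c("g1", "g2"),
                     kind = "arrhenius_E", attribute = "survival",
                     context = "single_driver")
  effC <- transform(effE, value = c(-0.02, -0.03), kind = "lnrr_co2")
  fits <- list(E = coral_meta(effE), C = coral_meta(effC))
  scen <- scenario_table(data.frame(
    rcp = c("RCP2.6", "RCP8.5", "RCP8.5"),
    period = c("near_term_2021_2040", "late_century_2081_2100",
               "end_of_century_2091_2100"),
    delta_T_C = c(1.8, 4.32, 0),
    delta_pco2_uatm = c(0, 0, 490)))
  proj <- project_all(fits, scen)
  expect_equal(nrow(proj), 3)
  expect_equal(sum(proj$kind == "arrhenius_E"), 2)
  expect_equal(sum(proj$kind == "lnrr_co2"), 1)
  expect_length(attr(proj, "gaps"), 0)

  # a scenario no fit can serve is reported as a gap, not an error
  co2_only <- list(C = fits$C)
  warm_scen <- scen[1, ]
  g <- project_all(co2_only, warm_scen)
  expect_equal(nrow(g), 0)
  expect_match(attr(g, "gaps"), "RCP2.6")

  # zero-delta scenarios project zero change and are non-significant
  zero <- project_all(fits, scenario_table(data.frame(
    rcp = "RCP2.6", period = "x", delta_T_C = 0, delta_pco2_uatm = 490)))
  expect_false(any(zero$kind == "arrhenius_E"))
})
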