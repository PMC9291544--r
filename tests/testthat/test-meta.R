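test_that("fewer than two effect sizes or non-positive variances are refused", {
  eff <- data.frame(value = 1, variance = 0.1, study_id = "s1", genus = "g1")
  expect_error(coral_meta(eff), "at least 2")
  eff2 <- data.frame(value = c(1, 2), variance = c(0.1, 0),
                     study_id = c("s1", "s2"), genus = c("g1", "g2"))
  expect_error(coral_meta(eff2), "variance")
})

test_that("with variance components fixed at zero the fit is the inverse-variance mean", {
  eff <- data.frame(value = c(0.5, 1.0), variance = c(0.1, 0.2),
                    study_id = c("a", "b"), genus = c("g1", "g2"))
  f <- coral_meta(eff, fixed_sigma2 = c(0, 0))
  expect_equal(f$estimate, 2 / 3, tolerance = 1e-10)
  expect_equal(f$se, sqrt(1 / (1 / 0.1 + 1 / 0.2)), tolerance = 1e-10)

  set.seed(31)
  big <- data.frame(value = rnorm(20, 1, 0.3), variance = runif(20, 0.01, 0.1),
                    study_id = sample(paste0("s", 1:8), 20, TRUE),
                    genus = sample(paste0("g", 1:4), 20, TRUE))
  fb <- coral_meta(big, fixed_sigma2 = c(0, 0))
  w <- 1 / big$variance
  expect_equal(fb$estimate, sum(w * big$value) / sum(w), tolerance = 1e-8)
})

test_that("the REML optimum dominates a grid search of the restricted likelihood", {
  set.seed(5)
  eff <- data.frame(value = rnorm(12, 1, 0.4), variance = runif(12, 0.01, 0.05),
                    study_id = sample(sprintf("s%d", 1:6), 12, TRUE),
                    genus = sample(sprintf("g%d", 1:4), 12, TRUE))
  f <- coral_meta(eff)
  # the independent evaluator reproduces the fitted restricted log-likelihood
  ll_hat <- reml_loglik(f$sigma2[["sigma2_study_id"]],
                        f$sigma2[["sigma2_genus"]],
                        eff$value, eff$variance, eff$study_id, eff$genus)
  expect_equal(ll_hat, as.numeric(logLik(f)), tolerance = 1e-6)
  grid <- reml_profile(f, grid_size = 25)
  expect_gte(ll_hat, max(grid$loglik) - 1e-8)
})

test_that("a single-level random factor is dropped and matches the reduced model", {
  set.seed(9)
  eff <- data.frame(value = rnorm(10, 0.8, 0.3), variance = runif(10, 0.02, 0.05),
                    study_id = sample(paste0("s", 1:5), 10, TRUE),
                    genus = "Acropora")
  expect_message(f <- coral_meta(eff), "single level")
  ref <- metafor::rma.mv(yi = eff$value, V = eff$variance,
                         random = list(~ 1 | study_id),
                         data = transform(eff, study_id = factor(study_id)),
                         method = "REML", test = "z")
  expect_equal(f$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$sigma2[["sigma2_study_id"]], ref$sigma2[1], tolerance = 1e-8)
  expect_equal(f$sigma2[["sigma2_genus"]], 0)
})

test_that("strata with mixed kinds are refused and coral_meta_by splits them", {
  eff <- data.frame(value = rnorm(8), variance = 0.05,
                    study_id = paste0("s", 1:8), genus = paste0("g", 1:8),
                    kind = rep(c("arrhenius_E", "lnrr_co2"), each = 4),
                    attribute = "survival",
                    context = "single_driver")
  expect_error(coral_meta(eff), "mix kinds")
  fits <- coral_meta_by(eff)
  expect_length(fits, 2)
  tab <- meta_table(fits)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$kind, c("arrhenius_E", "lnrr_co2"))
  expect_true(all(tab$k == 4))
})

test_that("leave-one-study-out flags exactly the engineered dominant study", {
  f <- coral_meta(outlier_effects())
  expect_true(f$significant)
  loso <- leave_one_study_out(f)
  expect_equal(nrow(loso), 6)
  expect_equal(loso$k[loso$study_id == "s6"], 5)
  expect_equal(loso$k[loso$study_id == "s1"], 7)
  expect_equal(loso$study_id[loso$verdict_changed], "s6")
})

test_that("leave-one-study-out reports no changes on a homogeneous data set", {
  eff <- data.frame(value = c(0.9, 1.0, 1.1, 0.95, 1.05, 1.0),
                    variance = 0.02, study_id = paste0("s", 1:6),
                    genus = rep(c("g1", "g2", "g3"), 2))
  f <- coral_meta(eff)
  loso <- leave_one_study_out(f)
  expect_false(any(loso$verdict_changed))
  small <- eff[1:2, ]
  expect_error(leave_one_study_out(coral_meta(small)), "3 distinct studies")
})

test_that("funnel data flags effects far outside the pooled distribution", {
  eff <- data.frame(value = c(rep(1, 9), 5), variance = 0.04,
                    study_id = paste0("s", 1:10),
                    genus = rep(c("g1", "g2"), 5))
  f <- coral_meta(eff)
  fd <- funnel_data(f)
  expect_equal(nrow(fd), 10)
  expect_false(fd$inside_funnel[10])
  # an effect exactly at the pooled estimate is always inside
  at <- transform(eff, value = f$estimate)
  expect_true(all(funnel_data(coral_meta(at))$inside_funnel))
})

test_that("model methods expose the fit the standard way", {
  f <- coral_meta(outlier_effects())
  expect_equal(unname(coef(f)), f$estimate)
  expect_equal(unname(sqrt(vcov(f)[1, 1])), f$se)
  ci <- confint(f)
  expect_lt(ci[1, "lower"], f$estimate)
  expect_gt(ci[1, "upper"], f$estimate)
  expect_output(print(f), "pooled estimate")
  expect_output(print(summary(f)), "z")
  expect_length(residuals(f), f$k)
})
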