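# Builders for small in-code fixtures shared across test files.

make_record <- function(study_id = "s1", genus = "Acropora",
                        attribute = "survival", arm_type = "warming",
                        control_mean = 10, control_sd = 1, control_n = 4,
                        treatment_mean = 8, treatment_sd = 1, treatment_n = 4,
                        t_control_C = 26.85, t_treatment_C = 28.85,
                        pco2_control_uatm = 400, pco2_treatment_uatm = 400) {
  data.frame(study_id = study_id, genus = genus, attribute = attribute,
             arm_type = arm_type, control_mean = control_mean,
             control_sd = control_sd, control_n = control_n,
             treatment_mean = treatment_mean, treatment_sd = treatment_sd,
             treatment_n = treatment_n, t_control_C = t_control_C,
             t_treatment_C = t_treatment_C,
             pco2_control_uatm = pco2_control_uatm,
             pco2_treatment_uatm = pco2_treatment_uatm,
             stringsAsFactors = FALSE)
}

make_quad <- function(mean_control = 10, mean_warming = 8, mean_co2 = 9,
                      mean_both = 6, sd = 1, n = 4, study_id = "s1",
                      genus = "Acropora", attribute = "calcification") {
  data.frame(study_id = study_id, genus = genus, attribute = attribute,
             mean_control = mean_control, mean_warming = mean_warming,
             mean_co2 = mean_co2, mean_both = mean_both,
             sd_control = sd, sd_warming = sd, sd_co2 = sd, sd_both = sd,
             n_control = n, n_warming = n, n_co2 = n, n_both = n,
             t_control_C = 27, t_treatment_C = 30,
             pco2_control_uatm = 400, pco2_treatment_uatm = 800,
             stringsAsFactors = FALSE)
}

# Effect table with a dominant, precise outlier study engineered so that
# dropping it (and only it) flips the pooled significance verdict.
outlier_effects <- function() {
  data.frame(
    value = c(0.08 + c(0.02, -0.01, 0.015, -0.02, 0.005),
              0.30 + c(0.01, 0, -0.01)),
    variance = c(rep(0.03, 5), rep(0.003, 3)),
    study_id = c(paste0("s", 1:5), rep("s6", 3)),
    genus = rep(c("g1", "g2", "g3", "g4"), 2),
    stringsAsFactors = FALSE)
}
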