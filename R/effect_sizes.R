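#' Per-experiment effect sizes for the coral meta-analysis
#'
#' Computes one effect size per record per applicable kind:
#' * `arrhenius_E` for warming contrasts (`arm_type` `"warming"` or
#'   `"both"`): the activation energy `E = ln(V_o/V_i) / (1/(k T_o) -
#'   1/(k T_i))` in eV, with `V_o`, `V_i` the control and treatment means and
#'   temperatures in Kelvin. A rate that declines under warming gives
#'   `E > 0`.
#' * `lnrr_co2` for CO2 contrasts (`arm_type` `"co2"` or `"both"`): the log
#'   response ratio per +100 uatm,
#'   `(ln x_exp - ln x_cont) / (pCO2_exp - pCO2_cont) * 100`; negative values
#'   mean decline per +100 uatm.
#'
#' Records whose `arm_type` is `"both"` measured the focal driver in the
#' presence of the other stressor and are labelled
#' `context = "under_co_stressor"`; single-driver records get
#' `context = "single_driver"`. Sampling variances come from the two-group
#' delta method for a log ratio,
#' `v_ln = SD_t^2/(n_t m_t^2) + SD_c^2/(n_c m_c^2)`, rescaled to the effect
#' scale (`v_ln / d^2` with `d` the 1/(kT) difference, or
#' `v_ln (100/dpCO2)^2`).
#'
#' @param records A `coral_experiments` data frame (see
#'   [experiment_records()]).
#' @param kinds Which effect kinds to compute.
#' @param variance_floor Value substituted (with a warning) when both arm SDs
#'   are zero and the delta-method variance degenerates to 0.
#' @param continuity Add `0.5/n` to non-positive means (survival proportions
#'   of zero) instead of failing; off by default.
#' @return A data frame of class `coral_effects` with columns `value`,
#'   `variance`, `kind`, `context`, `attribute`, `study_id`, `genus`,
#'   `delta_inv_kT`, `delta_pco2_uatm`.
#' @seealso [activation_energy()], [lnrr_co2()], [coral_meta()]
#' @export
#' @examples
#' rec <- data.frame(
#'   study_id = "s1", genus = "Acropora", attribute = "survival",
#'   arm_type = "warming", control_mean = 10, control_sd = 1, control_n = 4,
#'   treatment_mean = 8, treatment_sd = 1, treatment_n = 4,
#'   t_control_C = 26.85, t_treatment_C = 28.85,
#'   pco2_control_uatm = 400, pco2_treatment_uatm = 400)
#' effect_sizes(experiment_records(rec))
effect_sizes <- function(records, kinds = c("arrhenius_E", "lnrr_co2"),
                         variance_floor = 1e-8, continuity = FALSE) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  out <- list()
  if ("arrhenius_E" %in% kinds) {
    sub <- records[records$arm_type %in% c("warming", "both"), , drop = FALSE]
    if (nrow(sub)) {
      out[[length(out) + 1L]] <-
        activation_energy(sub, variance_floor = variance_floor,
                          continuity = continuity)
    }
  }
  if ("lnrr_co2" %in% kinds) {
    sub <- records[records$arm_type %in% c("co2", "both"), , drop = FALSE]
    if (nrow(sub)) {
      out[[length(out) + 1L]] <-
        lnrr_co2(sub, variance_floor = variance_floor, continuity = continuity)
    }
  }
  if (!length(out)) {
    .fail("no records with an applicable arm_type for kinds: ",
          paste(kinds, collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("coral_effects", "data.frame")
  res
}

.adjust_means <- function(m, n, continuity, label) {
  bad <- !is.finite(m) | m <= 0
  if (!any(bad)) return(m)
  if (!continuity) {
    .fail("non-positive ", label, " mean(s) in row(s) ",
          paste(which(bad), collapse = ", "),
          "; log ratios need positive means (see `continuity`)")
  }
  message("continuity correction (0.5/n) applied to ", sum(bad), " ",
          label, " mean(s)")
  m[bad] <- 0.5 / n[bad]
  m
}

.log_ratio_variance <- function(records) {
  if (any(records$control_n < 2 | records$treatment_n < 2)) {
    .fail("sampling variance needs n >= 2 in both arms (rows ",
          paste(which(records$control_n < 2 | records$treatment_n < 2),
                collapse = ", "), ")")
  }
  records$treatment_sd^2 / (records$treatment_n * records$treatment_mean^2) +
    records$control_sd^2 / (records$control_n * records$control_mean^2)
}

## applied on the final effect scale, after rescaling v_ln
.floor_variance <- function(v, variance_floor) {
  floored <- v <= 0
  if (any(floored)) {
    warning("both arm SDs are zero in ", sum(floored),
            " record(s); applying the variance floor ", variance_floor,
            call. = FALSE)
    v[floored] <- variance_floor
  }
  v
}

#' Activation-energy effect size for warming contrasts
#'
#' See [effect_sizes()] for the model. Requires `arm_type` `"warming"` or
#' `"both"`, positive means, and `t_treatment_C > t_control_C`.
#'
#' @inheritParams effect_sizes
#' @return A `coral_effects` data frame with `kind = "arrhenius_E"` (value in
#'   eV, variance in eV^2).
#' @export
activation_energy <- function(records, variance_floor = 1e-8,
                              continuity = FALSE) {
  records <- as.data.frame(records)
  if (!all(records$arm_type %in% c("warming", "both"))) {
    .fail("activation_energy needs arm_type 'warming' or 'both'")
  }
  d <- delta_inv_kT(records$t_control_C, records$t_treatment_C)
  if (any(d == 0)) {
    .fail("degenerate contrast: t_treatment_C equals t_control_C in row(s) ",
          paste(which(d == 0), collapse = ", "))
  }
  records$control_mean <-
    .adjust_means(records$control_mean, records$control_n, continuity, "control")
  records$treatment_mean <-
    .adjust_means(records$treatment_mean, records$treatment_n, continuity,
                  "treatment")
  value <- log(records$control_mean / records$treatment_mean) / d
  v_ln <- .log_ratio_variance(records)
  res <- data.frame(
    value = value,
    variance = .floor_variance(v_ln / d^2, variance_floor),
    kind = "arrhenius_E",
    context = ifelse(records$arm_type == "both", "under_co_stressor",
                     "single_driver"),
    attribute = records$attribute,
    study_id = records$study_id,
    genus = records$genus,
    delta_inv_kT = d,
    delta_pco2_uatm = NA_real_,
    stringsAsFactors = FALSE)
  class(res) <- c("coral_effects", "data.frame")
  res
}

#' Log response ratio per 100 uatm for CO2 contrasts
#'
#' See [effect_sizes()] for the model. Requires `arm_type` `"co2"` or
#' `"both"`, positive means, and `pco2_treatment_uatm > pco2_control_uatm`.
#'
#' @inheritParams effect_sizes
#' @return A `coral_effects` data frame with `kind = "lnrr_co2"` (value per
#'   +100 uatm).
#' @export
lnrr_co2 <- function(records, variance_floor = 1e-8, continuity = FALSE) {
  records <- as.data.frame(records)
  if (!all(records$arm_type %in% c("co2", "both"))) {
    .fail("lnrr_co2 needs arm_type 'co2' or 'both'")
  }
  dp <- records$pco2_treatment_uatm - records$pco2_control_uatm
  if (any(dp <= 0)) {
    .fail("degenerate contrast: pCO2 difference <= 0 in row(s) ",
          paste(which(dp <= 0), collapse = ", "))
  }
  records$control_mean <-
    .adjust_means(records$control_mean, records$control_n, continuity, "control")
  records$treatment_mean <-
    .adjust_means(records$treatment_mean, records$treatment_n, continuity,
                  "treatment")
  value <- (log(records$treatment_mean) - log(records$control_mean)) / dp * 100
  v_ln <- .log_ratio_variance(records)
  res <- data.frame(
    value = value,
    variance = .floor_variance(v_ln * (100 / dp)^2, variance_floor),
    kind = "lnrr_co2",
    context = ifelse(records$arm_type == "both", "under_co_stressor",
                     "single_driver"),
    attribute = records$attribute,
    study_id = records$study_id,
    genus = records$genus,
    delta_inv_kT = NA_real_,
    delta_pco2_uatm = dp,
    stringsAsFactors = FALSE)
  class(res) <- c("coral_effects", "data.frame")
  res
}

#' Delta-method sampling variance of a log-ratio effect size
#'
#' The two-group delta-method variance of a log response ratio,
#' `v_ln = SD_t^2/(n_t m_t^2) + SD_c^2/(n_c m_c^2)`, rescaled to the
#' requested effect scale: divided by the squared 1/(kT) difference for
#' `kind = "arrhenius_E"`, multiplied by `(100/dpCO2)^2` for
#' `kind = "lnrr_co2"`.
#'
#' @inheritParams effect_sizes
#' @param kind Effect-size kind the variance is scaled to.
#' @return Numeric vector of variances, one per record.
#' @export
effect_variance <- function(records, kind = c("arrhenius_E", "lnrr_co2"),
                            variance_floor = 1e-8) {
  kind <- match.arg(kind)
  records <- as.data.frame(records)
  v_ln <- .log_ratio_variance(records)
  v <- if (kind == "arrhenius_E") {
    d <- delta_inv_kT(records$t_control_C, records$t_treatment_C)
    v_ln / d^2
  } else {
    dp <- records$pco2_treatment_uatm - records$pco2_control_uatm
    v_ln * (100 / dp)^2
  }
  .floor_variance(v, variance_floor)
}
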