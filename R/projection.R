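#' Map a warming increment to a 1/(kT) difference
#'
#' Projections need the Arrhenius coordinate difference `d(1/kT)` that
#' corresponds to a warming of `delta_T` degrees C. Two sources are
#' supported:
#' * `analytic_at_baseline`: evaluate `1/(k T_b) - 1/(k (T_b + delta_T))`
#'   exactly at a configured baseline control temperature (default 27 C, the
#'   midpoint of the 24-30 C control range of tropical coral experiments).
#' * `fitted_from_data`: ordinary least squares of each record's observed
#'   `d(1/kT)` on its warming `delta_T` across a record table, mirroring how
#'   a heterogeneous data set (controls at many temperatures) maps degrees
#'   to the effect scale.
#'
#' @param records Optional `coral_experiments` table with warming contrasts;
#'   when `NULL` the analytic map at `baseline_temperature_C` is returned.
#' @param baseline_temperature_C Baseline for the analytic map (degrees C).
#' @return An object of class `arrhenius_map`; use [predict.arrhenius_map()]
#'   to evaluate it.
#' @export
#' @examples
#' m <- fit_arrhenius_map(baseline_temperature_C = 27)
#' predict(m, delta_T = 1) # about 0.1284 per eV
fit_arrhenius_map <- function(records = NULL, baseline_temperature_C = 27) {
  if (is.null(records) || !nrow(records)) {
    out <- list(source = "analytic_at_baseline",
                baseline_temperature_C = baseline_temperature_C)
    class(out) <- "arrhenius_map"
    return(out)
  }
  records <- as.data.frame(records)
  warm <- records[records$arm_type %in% c("warming", "both"), , drop = FALSE]
  if (nrow(warm) < 2) .fail("need at least 2 warming records to fit the map")
  dT <- warm$t_treatment_C - warm$t_control_C
  if (length(unique(dT)) < 2) {
    .fail("all warming increments identical; the linear map is singular ",
          "(use the analytic map instead)")
  }
  d <- delta_inv_kT(warm$t_control_C, warm$t_treatment_C)
  ols <- lm(d ~ dT)
  out <- list(source = "fitted_from_data",
              slope = unname(coef(ols)[2]),
              intercept = unname(coef(ols)[1]),
              n = nrow(warm))
  class(out) <- "arrhenius_map"
  out
}

#' @export
print.arrhenius_map <- function(x, ...) {
  if (x$source == "analytic_at_baseline") {
    cat("Arrhenius map: analytic at baseline", x$baseline_temperature_C,
        "C\n")
  } else {
    cat(sprintf("Arrhenius map: OLS fit on %d records, d(1/kT) = %.5g + %.5g * dT\n",
                x$n, x$intercept, x$slope))
  }
  invisible(x)
}

#' Evaluate an Arrhenius map at warming increments
#'
#' @param object An `arrhenius_map`.
#' @param delta_T Warming increments in degrees C.
#' @param ... Unused.
#' @return `d(1/kT)` values in 1/eV.
#' @export
predict.arrhenius_map <- function(object, delta_T, ...) {
  if (object$source == "analytic_at_baseline") {
    delta_inv_kT(object$baseline_temperature_C,
                 object$baseline_temperature_C + delta_T)
  } else {
    object$intercept + object$slope * delta_T
  }
}

.meta_estimate <- function(object, kind) {
  if (inherits(object, "coral_meta")) {
    if (!is.na(object$kind) && !identical(object$kind, kind)) {
      .fail("meta result has kind '", object$kind, "', expected '", kind, "'")
    }
    list(estimate = object$estimate, se = object$se,
         attribute = object$attribute, context = object$context)
  } else if (is.numeric(object)) {
    est <- unname(object[1])
    se <- if (length(object) >= 2) unname(object[2]) else 0
    list(estimate = est, se = se, attribute = NA_character_,
         context = NA_character_)
  } else {
    .fail("expected a coral_meta object or a numeric c(estimate, se)")
  }
}

.pc_from_exponent <- function(x) 100 * (exp(x) - 1)

#' Expected percent change under a warming increment
#'
#' Back-transforms a pooled activation energy to the expected percent change
#' of the attribute at a warming of `delta_T` degrees C:
#' `change% = 100 (e^{-E d(1/kT)} - 1)`, so a positive `E` (decline under
#' warming) yields a negative change and the decline can never exceed 100%.
#' CI bounds back-transform the Wald bounds `E +/- z se`; the exponential is
#' monotone, so bound order is preserved.
#'
#' @param object A `coral_meta` fit with `kind = "arrhenius_E"`, or a numeric
#'   `c(estimate, se)` in eV.
#' @param delta_T Warming increment(s), degrees C (>= 0).
#' @param map An [fit_arrhenius_map()] object; default analytic at
#'   `baseline_temperature_C`.
#' @param baseline_temperature_C Baseline used when `map` is missing.
#' @param z Normal quantile for the CI.
#' @return A data frame of class `coral_projection` with `delta_T_C`,
#'   `percent_change` (negative = decline), `ci_low`, `ci_high`,
#'   `significant`, plus labels.
#' @export
#' @examples
#' # pooled survival E of 0.7 eV at the late-century RCP8.5 MHW intensity:
#' percent_change_temp(c(0.7, 0), delta_T = 4.32)
percent_change_temp <- function(object, delta_T,
                                map = fit_arrhenius_map(
                                  baseline_temperature_C = baseline_temperature_C),
                                baseline_temperature_C = 27, z = 1.96) {
  est <- .meta_estimate(object, "arrhenius_E")
  stopifnot(all(delta_T >= 0))
  d <- predict(map, delta_T)
  pc <- .pc_from_exponent(-est$estimate * d)
  ## exponent is decreasing in E: upper E bound -> lower change bound
  lo <- .pc_from_exponent(-(est$estimate + z * est$se) * d)
  hi <- .pc_from_exponent(-(est$estimate - z * est$se) * d)
  res <- data.frame(
    attribute = est$attribute, context = est$context, kind = "arrhenius_E",
    delta_T_C = delta_T, delta_pco2_uatm = NA_real_,
    percent_change = pc, ci_low = pmin(lo, hi), ci_high = pmax(lo, hi),
    stringsAsFactors = FALSE)
  res$significant <- res$ci_low > 0 | res$ci_high < 0
  class(res) <- c("coral_projection", "data.frame")
  res
}

#' Expected percent change under a pCO2 increment
#'
#' Back-transforms a pooled log response ratio per +100 uatm to the expected
#' percent change at a pCO2 increase of `delta_pco2` uatm:
#' `change% = 100 (e^{lnrr delta/100} - 1)`; a negative pooled ratio yields a
#' decline.
#'
#' @param object A `coral_meta` fit with `kind = "lnrr_co2"`, or a numeric
#'   `c(estimate, se)` per +100 uatm.
#' @param delta_pco2 pCO2 increment(s), uatm (>= 0).
#' @param z Normal quantile for the CI.
#' @return A `coral_projection` data frame (see [percent_change_temp()]).
#' @export
#' @examples
#' percent_change_co2(c(-0.0197, 0), delta_pco2 = 490) # about -9.2%
percent_change_co2 <- function(object, delta_pco2, z = 1.96) {
  est <- .meta_estimate(object, "lnrr_co2")
  stopifnot(all(delta_pco2 >= 0))
  pc <- .pc_from_exponent(est$estimate * delta_pco2 / 100)
  lo <- .pc_from_exponent((est$estimate - z * est$se) * delta_pco2 / 100)
  hi <- .pc_from_exponent((est$estimate + z * est$se) * delta_pco2 / 100)
  res <- data.frame(
    attribute = est$attribute, context = est$context, kind = "lnrr_co2",
    delta_T_C = NA_real_, delta_pco2_uatm = delta_pco2,
    percent_change = pc, ci_low = pmin(lo, hi), ci_high = pmax(lo, hi),
    stringsAsFactors = FALSE)
  res$significant <- res$ci_low > 0 | res$ci_high < 0
  class(res) <- c("coral_projection", "data.frame")
  res
}

#' Percent-change projections from a fitted meta-analysis
#'
#' Convenience `predict` method: supply either `delta_T` (for activation
#' energy fits) or `delta_pco2` (for CO2 log-ratio fits).
#'
#' @param object A `coral_meta` object.
#' @param delta_T Warming increments, degrees C.
#' @param delta_pco2 pCO2 increments, uatm.
#' @param map,baseline_temperature_C See [percent_change_temp()].
#' @param ... Unused.
#' @return A `coral_projection` data frame.
#' @export
predict.coral_meta <- function(object, delta_T = NULL, delta_pco2 = NULL,
                               map = NULL, baseline_temperature_C = 27, ...) {
  if (!is.null(delta_T)) {
    if (is.null(map)) {
      map <- fit_arrhenius_map(baseline_temperature_C = baseline_temperature_C)
    }
    percent_change_temp(object, delta_T, map = map)
  } else if (!is.null(delta_pco2)) {
    percent_change_co2(object, delta_pco2)
  } else {
    .fail("supply delta_T or delta_pco2")
  }
}

#' Minimum driver increase producing a significant percent change
#'
#' Scans increments `step, 2 step, ...` up to `cap` and reports the first at
#' which the back-transformed CI excludes zero — the statistical sensitivity
#' of an attribute to warming (degrees C) or acidification (uatm). Because
#' the back-transform is monotone, under the `"exact"` rule the answer is
#' either the first scanned step (when the effect's own CI excludes zero) or
#' does not exist; the `"rounded"` rule requires exclusion after rounding the
#' percent bounds to `digits` decimals, so the threshold is reached only once
#' the projected change grows past reporting precision, yielding finite
#' intermediate thresholds.
#'
#' @param object A `coral_meta` fit (or `c(estimate, se)` with `kind` implied
#'   by `driver`).
#' @param driver `"temperature"` or `"co2"`.
#' @param step Scan increment (degrees C or uatm).
#' @param cap Largest increment scanned.
#' @param precision_rule `"exact"` (strict CI exclusion) or `"rounded"`.
#' @param digits Decimals the percent bounds are rounded to under
#'   `"rounded"`.
#' @param map,baseline_temperature_C Temperature mapping (see
#'   [percent_change_temp()]).
#' @return A one-row data frame: `attribute`, `driver`, `min_delta` (`NA`
#'   when no scanned increment is significant), `percent_change_at_min`.
#' @export
min_significant_delta <- function(object, driver = c("temperature", "co2"),
                                  step = if (driver == "temperature") 0.01 else 1,
                                  cap = if (driver == "temperature") 13 else 800,
                                  precision_rule = c("exact", "rounded"),
                                  digits = 0, map = NULL,
                                  baseline_temperature_C = 27) {
  driver <- match.arg(driver)
  precision_rule <- match.arg(precision_rule)
  stopifnot(step > 0, is.finite(cap))
  if (driver == "temperature" && is.null(map)) {
    map <- fit_arrhenius_map(baseline_temperature_C = baseline_temperature_C)
  }
  deltas <- seq(step, cap, by = step)
  attribute <- if (inherits(object, "coral_meta")) object$attribute
  else NA_character_
  for (delta in deltas) {
    proj <- if (driver == "temperature") {
      percent_change_temp(object, delta, map = map)
    } else {
      percent_change_co2(object, delta)
    }
    lo <- proj$ci_low
    hi <- proj$ci_high
    if (precision_rule == "rounded") {
      lo <- round(lo, digits)
      hi <- round(hi, digits)
    }
    if (lo > 0 || hi < 0) {
      return(data.frame(attribute = attribute, driver = driver,
                        min_delta = delta,
                        percent_change_at_min = proj$percent_change,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(attribute = attribute, driver = driver, min_delta = NA_real_,
             percent_change_at_min = NA_real_, stringsAsFactors = FALSE)
}

#' Assemble the full scenario projection table
#'
#' Crosses fitted meta-analyses with a scenario table: every activation
#' energy fit is projected at each scenario's `delta_T_C > 0` and every CO2
#' log-ratio fit at each `delta_pco2_uatm > 0`. Attributes requested by a
#' scenario but lacking a fitted stratum are collected in the `gaps`
#' attribute rather than failing.
#'
#' @param fits A list of `coral_meta` objects (see [coral_meta_by()]).
#' @param scenarios A scenario table (see [scenario_table()]).
#' @param map,baseline_temperature_C Temperature mapping.
#' @return A `coral_projection` data frame with scenario labels, one row per
#'   fit x applicable scenario; `attr(, "gaps")` lists skipped combinations.
#' @export
project_all <- function(fits, scenarios,
                        map = fit_arrhenius_map(
                          baseline_temperature_C = baseline_temperature_C),
                        baseline_temperature_C = 27) {
  scenarios <- scenario_table(scenarios)
  if (inherits(fits, "coral_meta")) fits <- list(fits)
  rows <- list()
  gaps <- character(0)
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    label <- paste0(sc$rcp, "/", sc$period)
    applicable <- FALSE
    for (nm in names(fits)) {
      f <- fits[[nm]]
      proj <- if (identical(f$kind, "arrhenius_E") && sc$delta_T_C > 0) {
        percent_change_temp(f, sc$delta_T_C, map = map)
      } else if (identical(f$kind, "lnrr_co2") && sc$delta_pco2_uatm > 0) {
        percent_change_co2(f, sc$delta_pco2_uatm)
      } else {
        NULL
      }
      if (is.null(proj)) next
      applicable <- TRUE
      proj$rcp <- sc$rcp
      proj$period <- sc$period
      rows[[length(rows) + 1L]] <- proj
    }
    if (!applicable) gaps <- c(gaps, paste0(label, ": no applicable fit"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(attribute = character(0), context = character(0),
               kind = character(0), delta_T_C = numeric(0),
               delta_pco2_uatm = numeric(0), percent_change = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               significant = logical(0), rcp = character(0),
               period = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  class(out) <- c("coral_projection", "data.frame")
  out
}
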