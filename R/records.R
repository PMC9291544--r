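#' Coral attribute levels recognised by the pipeline
#'
#' The eight holobiont performance attributes the meta-analysis pools over.
#'
#' @return Character vector of attribute names.
#' @export
coral_attributes <- function() {
  c("symbiont_density", "chla", "photochemical_efficiency", "photosynthesis",
    "respiration", "calcification", "growth", "survival")
}

.arm_types <- c("warming", "co2", "both")

.record_columns <- c(
  "study_id", "genus", "species", "attribute", "arm_type",
  "control_mean", "control_sd", "control_n",
  "treatment_mean", "treatment_sd", "treatment_n",
  "t_control_C", "t_treatment_C",
  "pco2_control_uatm", "pco2_treatment_uatm", "duration_days"
)

.required_record_columns <- setdiff(.record_columns, c("species", "duration_days"))

.quad_arms <- c("control", "warming", "co2", "both")

.quad_columns <- c(
  "study_id", "genus", "attribute",
  paste0("mean_", .quad_arms), paste0("sd_", .quad_arms), paste0("n_", .quad_arms),
  "t_control_C", "t_treatment_C", "pco2_control_uatm", "pco2_treatment_uatm"
)

## Collect row-level validation messages for two-arm records.
.validate_record_rows <- function(df) {
  msgs <- character(0)
  bad <- logical(nrow(df))
  flag <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      rows <- which(idx)
      msgs <<- c(msgs, paste0("row ", paste(rows, collapse = ", "), ": ", what))
      bad[rows] <<- TRUE
    }
  }
  flag(!(df$attribute %in% coral_attributes()), "unknown attribute")
  flag(!(df$arm_type %in% .arm_types), "unknown arm_type")
  flag(!is.finite(df$control_n) | df$control_n < 1 |
         !is.finite(df$treatment_n) | df$treatment_n < 1,
       "sample sizes must be >= 1")
  flag(df$control_sd < 0 | df$treatment_sd < 0, "negative SD")
  flag(!is.finite(df$control_mean) | df$control_mean <= 0 |
         !is.finite(df$treatment_mean) | df$treatment_mean <= 0,
       "non-positive mean (log response ratios need strictly positive means)")
  warm <- df$arm_type %in% c("warming", "both")
  flag(warm & !(df$t_treatment_C > df$t_control_C),
       "warming contrast requires t_treatment_C > t_control_C")
  co2 <- df$arm_type %in% c("co2", "both")
  flag(co2 & !(df$pco2_treatment_uatm > df$pco2_control_uatm),
       "CO2 contrast requires pco2_treatment_uatm > pco2_control_uatm")
  list(bad = bad, messages = msgs)
}

#' Validate a table of two-arm coral experiment records
#'
#' Checks a data frame of control/treatment contrasts against the record
#' schema: one row per experiment with arm summaries (mean, SD, n), the
#' treatment temperatures (degrees C) and pCO2 levels (uatm), the measured
#' attribute, and study/genus labels. Rows violating the invariants
#' (non-positive means, n < 1, negative SDs, non-warming "warming" contrasts,
#' ...) are either dropped with a warning (`strict = FALSE`) or abort the call
#' with the offending row numbers (`strict = TRUE`). Valid rows are returned
#' identically in both modes.
#'
#' @param df Data frame with (at least) the required record columns; see
#'   Details.
#' @param strict Logical; abort on any invalid row instead of dropping it.
#' @return The validated rows as a data frame of class `coral_experiments`,
#'   with an attribute `dropped` holding the messages for excluded rows.
#' @details Required columns: `study_id`, `genus`, `attribute`, `arm_type`
#'   (one of `"warming"`, `"co2"`, `"both"`), `control_mean`, `control_sd`,
#'   `control_n`, `treatment_mean`, `treatment_sd`, `treatment_n`,
#'   `t_control_C`, `t_treatment_C`, `pco2_control_uatm`,
#'   `pco2_treatment_uatm`. Optional: `species`, `duration_days`.
#' @export
experiment_records <- function(df, strict = FALSE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.required_record_columns, names(df))
  if (length(missing_cols)) {
    .fail("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"species" %in% names(df)) df$species <- NA_character_
  if (!"duration_days" %in% names(df)) df$duration_days <- NA_real_
  num <- setdiff(.record_columns,
                 c("study_id", "genus", "species", "attribute", "arm_type"))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in c("study_id", "genus", "species", "attribute", "arm_type")) {
    df[[cl]] <- as.character(df[[cl]])
  }
  chk <- .validate_record_rows(df)
  if (length(chk$messages)) {
    if (strict) {
      .fail("invalid experiment records:\n  ",
            paste(chk$messages, collapse = "\n  "))
    }
    warning("dropping ", sum(chk$bad), " invalid record(s):\n  ",
            paste(chk$messages, collapse = "\n  "), call. = FALSE)
  }
  out <- df[!chk$bad, .record_columns, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- chk$messages
  class(out) <- c("coral_experiments", "data.frame")
  out
}

#' Read two-arm experiment records from a CSV file
#'
#' Reads a comma-separated UTF-8 file with a header row and validates it with
#' [experiment_records()]. Because deposited data sets rarely share column
#' names, a `mapping` can rename columns before validation: a named character
#' vector `c(schema_name = "file_column", ...)`, or the path to a two-column
#' CSV (`field`, `column`) with the same content.
#'
#' @param path Path to the records CSV.
#' @param mapping Optional column mapping (named character vector or CSV path).
#' @param strict Passed to [experiment_records()].
#' @return A `coral_experiments` data frame.
#' @export
read_experiments <- function(path, mapping = NULL, strict = FALSE) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .apply_mapping(df, mapping)
  experiment_records(df, strict = strict)
}

.apply_mapping <- function(df, mapping) {
  if (is.null(mapping)) return(df)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    m <- read.csv(mapping, stringsAsFactors = FALSE)
    if (!all(c("field", "column") %in% names(m))) {
      .fail("mapping file needs columns 'field' and 'column'")
    }
    mapping <- setNames(m$column, m$field)
  }
  missing_src <- setdiff(unname(mapping), names(df))
  if (length(missing_src)) {
    .fail("mapping refers to absent column(s): ",
          paste(missing_src, collapse = ", "))
  }
  for (i in seq_along(mapping)) {
    names(df)[names(df) == mapping[[i]]] <- names(mapping)[i]
  }
  df
}

#' Write experiment records to CSV
#'
#' Plain-CSV writer whose output round-trips losslessly through
#' [read_experiments()].
#'
#' @param x A `coral_experiments` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------ quads

.validate_quad_rows <- function(df) {
  msgs <- character(0)
  bad <- logical(nrow(df))
  flag <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      rows <- which(idx)
      msgs <<- c(msgs, paste0("row ", paste(rows, collapse = ", "), ": ", what))
      bad[rows] <<- TRUE
    }
  }
  for (arm in .quad_arms) {
    m <- df[[paste0("mean_", arm)]]
    s <- df[[paste0("sd_", arm)]]
    n <- df[[paste0("n_", arm)]]
    flag(!is.finite(m) | m <= 0, paste0(arm, " arm mean must be > 0"))
    flag(!is.finite(s) | s < 0, paste0(arm, " arm SD must be >= 0"))
    flag(!is.finite(n) | n < 2,
         paste0(arm, " arm needs n >= 2 (pooled SD requires n - 1 >= 1)"))
  }
  list(bad = bad, messages = msgs)
}

#' Validate a table of full-factorial warming x CO2 quads
#'
#' A factorial quad is one experiment with all four arms: control, warming
#' alone, elevated CO2 alone, and both stressors. Each arm carries a mean, SD
#' and sample size (`mean_control`, `sd_control`, `n_control`,
#' `mean_warming`, ..., `n_both`), plus the treatment temperature and pCO2
#' levels. All four arm means must be positive and all n at least 2.
#'
#' @param df Data frame in the wide quad schema.
#' @param strict Abort on invalid rows instead of dropping them.
#' @return A data frame of class `coral_quads`.
#' @export
factorial_quads <- function(df, strict = FALSE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.quad_columns, names(df))
  if (length(missing_cols)) {
    .fail("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  num <- setdiff(.quad_columns, c("study_id", "genus", "attribute"))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  chk <- .validate_quad_rows(df)
  if (length(chk$messages)) {
    if (strict) {
      .fail("invalid factorial quads:\n  ",
            paste(chk$messages, collapse = "\n  "))
    }
    warning("dropping ", sum(chk$bad), " invalid quad(s):\n  ",
            paste(chk$messages, collapse = "\n  "), call. = FALSE)
  }
  out <- df[!chk$bad, .quad_columns, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coral_quads", "data.frame")
  out
}

#' Read factorial quads from a CSV file
#'
#' @inheritParams read_experiments
#' @return A `coral_quads` data frame.
#' @export
read_factorial <- function(path, mapping = NULL, strict = FALSE) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- .apply_mapping(read.csv(path, stringsAsFactors = FALSE), mapping)
  factorial_quads(df, strict = strict)
}

#' Assemble factorial quads from a long table of experiment arms
#'
#' Takes a long table with one row per arm (`experiment_id`, `arm` in
#' `control`/`warming`/`co2`/`both`, `mean`, `sd`, `n`, labels, temperatures,
#' pCO2) and assembles complete quads. Experiments missing any of the four
#' arms are not forced into quads; their non-control arms are returned as
#' ordinary two-arm records against the control arm, so partially factorial
#' designs still contribute to the single-driver effect sizes.
#'
#' @param arms Long-format data frame; required columns `experiment_id`,
#'   `study_id`, `genus`, `attribute`, `arm`, `mean`, `sd`, `n`,
#'   `t_control_C`, `t_treatment_C`, `pco2_control_uatm`,
#'   `pco2_treatment_uatm`.
#' @return A list with elements `quads` (class `coral_quads`) and `records`
#'   (class `coral_experiments`, the fallback two-arm contrasts).
#' @export
quads_from_arms <- function(arms) {
  need <- c("experiment_id", "study_id", "genus", "attribute", "arm",
            "mean", "sd", "n", "t_control_C", "t_treatment_C",
            "pco2_control_uatm", "pco2_treatment_uatm")
  missing_cols <- setdiff(need, names(arms))
  if (length(missing_cols)) {
    .fail("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  quad_rows <- list()
  rec_rows <- list()
  for (id in unique(arms$experiment_id)) {
    a <- arms[arms$experiment_id == id, , drop = FALSE]
    have <- .quad_arms %in% a$arm
    pick <- function(arm, col) a[[col]][match(arm, a$arm)]
    if (all(have)) {
      quad_rows[[length(quad_rows) + 1L]] <- data.frame(
        study_id = a$study_id[1], genus = a$genus[1], attribute = a$attribute[1],
        mean_control = pick("control", "mean"), mean_warming = pick("warming", "mean"),
        mean_co2 = pick("co2", "mean"), mean_both = pick("both", "mean"),
        sd_control = pick("control", "sd"), sd_warming = pick("warming", "sd"),
        sd_co2 = pick("co2", "sd"), sd_both = pick("both", "sd"),
        n_control = pick("control", "n"), n_warming = pick("warming", "n"),
        n_co2 = pick("co2", "n"), n_both = pick("both", "n"),
        t_control_C = a$t_control_C[1], t_treatment_C = a$t_treatment_C[1],
        pco2_control_uatm = a$pco2_control_uatm[1],
        pco2_treatment_uatm = a$pco2_treatment_uatm[1],
        stringsAsFactors = FALSE)
    } else if ("control" %in% a$arm) {
      for (arm in intersect(c("warming", "co2", "both"), a$arm)) {
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          study_id = a$study_id[1], genus = a$genus[1],
          attribute = a$attribute[1], arm_type = arm,
          control_mean = pick("control", "mean"), control_sd = pick("control", "sd"),
          control_n = pick("control", "n"),
          treatment_mean = pick(arm, "mean"), treatment_sd = pick(arm, "sd"),
          treatment_n = pick(arm, "n"),
          t_control_C = a$t_control_C[1], t_treatment_C = a$t_treatment_C[1],
          pco2_control_uatm = a$pco2_control_uatm[1],
          pco2_treatment_uatm = a$pco2_treatment_uatm[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  quads <- if (length(quad_rows)) {
    factorial_quads(do.call(rbind, quad_rows))
  } else {
    factorial_quads(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, length(.quad_columns))), .quad_columns))
  }
  records <- if (length(rec_rows)) {
    experiment_records(do.call(rbind, rec_rows))
  } else {
    NULL
  }
  list(quads = quads, records = records)
}

## ------------------------------------------------------------- scenarios

#' Read a scenario table
#'
#' Scenario tables carry one row per RCP x period with the MHW warming above
#' present (`delta_T_C`, degrees C) and/or the CO2 increase above present
#' (`delta_pco2_uatm`, uatm). Both deltas must be non-negative and at least
#' one must be positive per row.
#'
#' @param path CSV with columns `rcp`, `period`, `delta_T_C`,
#'   `delta_pco2_uatm`.
#' @return A validated data frame.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  scenario_table(df)
}

#' Validate a scenario table given as a data frame
#'
#' @param df Data frame with columns `rcp`, `period`, `delta_T_C`,
#'   `delta_pco2_uatm` (missing delta columns are filled with 0).
#' @return The validated data frame.
#' @seealso [rcp_co2_scenarios()]
#' @export
scenario_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("rcp", "period") %in% names(df))) {
    .fail("scenario table needs columns 'rcp' and 'period'")
  }
  if (!"delta_T_C" %in% names(df)) df$delta_T_C <- 0
  if (!"delta_pco2_uatm" %in% names(df)) df$delta_pco2_uatm <- 0
  df$delta_T_C <- as.numeric(df$delta_T_C)
  df$delta_pco2_uatm <- as.numeric(df$delta_pco2_uatm)
  bad <- !is.finite(df$delta_T_C) | !is.finite(df$delta_pco2_uatm) |
    df$delta_T_C < 0 | df$delta_pco2_uatm < 0
  if (any(bad)) {
    .fail("scenario rows with negative or missing deltas: ",
          paste(which(bad), collapse = ", "))
  }
  df
}

#' End-of-century CO2 increments under the four RCPs
#'
#' The projected end-of-century (2091-2100) increases in seawater pCO2 above
#' present-day levels: +63 uatm (RCP2.6), +173 uatm (RCP4.5), +276 uatm
#' (RCP6.0) and +490 uatm (RCP8.5).
#'
#' @return A scenario table (see [scenario_table()]) with `delta_T_C = 0`.
#' @export
rcp_co2_scenarios <- function() {
  scenario_table(data.frame(
    rcp = c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5"),
    period = "end_of_century_2091_2100",
    delta_T_C = 0,
    delta_pco2_uatm = c(63, 173, 276, 490),
    stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------- config

#' Pipeline configuration
#'
#' Bundles the tunable constants of the pipeline in one list. All
#' randomness downstream of [run_pipeline()] flows from `seed`.
#'
#' @param baseline_temperature_C Reference control temperature for the
#'   analytic temperature-to-1/(kT) mapping (degrees C). 27 is the midpoint
#'   of the control range typical of tropical coral experiments (24-30 C).
#' @param sensitivity_step_C Temperature increment of the threshold search
#'   (degrees C).
#' @param sensitivity_step_uatm pCO2 increment of the threshold search (uatm).
#' @param sensitivity_cap_C Largest warming scanned (degrees C).
#' @param sensitivity_cap_uatm Largest pCO2 increase scanned (uatm).
#' @param alpha Significance level for all Wald tests and intervals.
#' @param mhw_percentile Baseline percentile defining a marine heatwave.
#' @param mhw_min_duration Minimum run length (days) counted as an event.
#' @param variance_floor Sampling-variance floor applied when both arm SDs
#'   are zero.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `coral_config`.
#' @export
pipeline_config <- function(baseline_temperature_C = 27,
                            sensitivity_step_C = 0.01,
                            sensitivity_step_uatm = 1,
                            sensitivity_cap_C = 13,
                            sensitivity_cap_uatm = 800,
                            alpha = 0.05,
                            mhw_percentile = 90,
                            mhw_min_duration = 1,
                            variance_floor = 1e-8,
                            seed = 1L) {
  stopifnot(mhw_percentile > 0, mhw_percentile < 100,
            sensitivity_step_C > 0, sensitivity_step_uatm > 0,
            alpha > 0, alpha < 1)
  structure(list(
    boltzmann_k = .k_boltzmann,
    baseline_temperature_C = baseline_temperature_C,
    sensitivity_step_C = sensitivity_step_C,
    sensitivity_step_uatm = sensitivity_step_uatm,
    sensitivity_cap_C = sensitivity_cap_C,
    sensitivity_cap_uatm = sensitivity_cap_uatm,
    alpha = alpha,
    mhw_percentile = mhw_percentile,
    mhw_min_duration = mhw_min_duration,
    variance_floor = variance_floor,
    seed = as.integer(seed)), class = "coral_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected; absent keys keep their [pipeline_config()]
#' defaults.
#'
#' @param path A `.json`, `.yml` or `.yaml` file of configuration values.
#' @return A `coral_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      .fail("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    .fail("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}
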