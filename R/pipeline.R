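## Run one pipeline stage with contextual error reporting.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .fail("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full projection pipeline
#'
#' Executes every stage end to end — effect sizes, interaction
#' classification, multilevel meta-analyses, scenario projections with the
#' threshold-sensitivity search, and MHW detection — and writes one tidy CSV
#' per stage plus a machine-readable JSON run manifest. Inputs that are not
#' supplied are simulated from the configuration seed, so
#' `run_pipeline(output_dir = d)` exercises the whole pipeline on synthetic
#' data with known truth; all outputs are deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()] list.
#' @param records Two-arm records (`coral_experiments`); simulated when
#'   `NULL`.
#' @param quads Factorial quads (`coral_quads`); simulated when `NULL`.
#' @param scenarios Scenario table; defaults to [rcp_co2_scenarios()].
#' @param sst Daily SST input as returned by [sim_sst()] (list with `data`
#'   and `baseline`); simulated when `NULL`.
#' @param output_dir Directory the CSVs and manifest are written to (created
#'   if needed).
#' @param strict Passed to the record validators.
#' @return Invisibly, a list with the in-memory stage results (`effects`,
#'   `interactions`, `fits`, `meta`, `projections`, `sensitivity`,
#'   `mhw_events`, `mhw_annual`) and `paths` of the written files.
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL,
                         quads = NULL, scenarios = NULL, sst = NULL,
                         output_dir = ".", strict = FALSE) {
  stopifnot(inherits(config, "coral_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (is.null(records)) {
    records <- .stage("simulate_records",
                      sim_experiments(seed = config$seed)$records)
  }
  if (is.null(quads)) {
    quads <- .stage("simulate_quads",
                    sim_factorial(seed = config$seed + 1L)$quads)
  }
  if (is.null(scenarios)) scenarios <- rcp_co2_scenarios()
  scenarios <- scenario_table(scenarios)
  if (is.null(sst)) {
    sst <- .stage("simulate_sst", sim_sst(seed = config$seed + 2L))
  }

  effects <- .stage("effect_sizes",
                    effect_sizes(records,
                                 variance_floor = config$variance_floor))
  inter <- .stage("interactions", interaction_effects(quads))
  inter_sum <- interaction_summary(inter)
  fits <- .stage("meta", coral_meta_by(effects, alpha = config$alpha))
  meta <- meta_table(fits)
  map <- fit_arrhenius_map(
    baseline_temperature_C = config$baseline_temperature_C)
  proj <- .stage("projection", project_all(fits, scenarios, map = map))
  sens <- .stage("sensitivity", {
    rows <- lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (identical(f$kind, "arrhenius_E")) {
        min_significant_delta(f, "temperature",
                              step = config$sensitivity_step_C,
                              cap = config$sensitivity_cap_C, map = map)
      } else {
        min_significant_delta(f, "co2",
                              step = config$sensitivity_step_uatm,
                              cap = config$sensitivity_cap_uatm)
      }
    })
    do.call(rbind, rows)
  })
  thr <- .stage("mhw_threshold",
                mhw_threshold(sst$data$sst, baseline = sst$baseline,
                              probs = config$mhw_percentile))
  ev <- .stage("mhw_events",
               mhw_events(sst$data$date, sst$data$sst, thr,
                          min_duration = config$mhw_min_duration))
  ann <- .stage("mhw_annual",
                mhw_annual_stats(sst$data$date, sst$data$sst, thr,
                                 min_duration = config$mhw_min_duration,
                                 events = ev))

  paths <- c(
    effects = file.path(output_dir, "effects.csv"),
    interactions = file.path(output_dir, "interactions.csv"),
    interaction_summary = file.path(output_dir, "interaction_summary.csv"),
    meta = file.path(output_dir, "meta.csv"),
    projections = file.path(output_dir, "projections.csv"),
    sensitivity = file.path(output_dir, "sensitivity.csv"),
    mhw_events = file.path(output_dir, "mhw_events.csv"),
    mhw_annual = file.path(output_dir, "mhw_annual.csv"),
    manifest = file.path(output_dir, "manifest.json"))
  write.csv(as.data.frame(effects), paths["effects"], row.names = FALSE)
  write.csv(as.data.frame(inter), paths["interactions"], row.names = FALSE)
  write.csv(inter_sum, paths["interaction_summary"], row.names = FALSE)
  write.csv(meta, paths["meta"], row.names = FALSE)
  write.csv(as.data.frame(proj), paths["projections"], row.names = FALSE)
  write.csv(sens, paths["sensitivity"], row.names = FALSE)
  write.csv(as.data.frame(ev), paths["mhw_events"], row.names = FALSE)
  write.csv(as.data.frame(ann), paths["mhw_annual"], row.names = FALSE)
  manifest <- list(
    package = "coralMHW",
    version = as.character(utils::packageVersion("coralMHW")),
    seed = config$seed,
    config = unclass(config),
    n_records = nrow(records), n_quads = nrow(quads),
    n_effects = nrow(effects), n_meta = nrow(meta),
    mhw_threshold = unname(thr),
    gaps = attr(proj, "gaps"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(effects = effects, interactions = inter,
                 interaction_summary = inter_sum, fits = fits, meta = meta,
                 projections = proj, sensitivity = sens, mhw_events = ev,
                 mhw_annual = ann, paths = paths))
}
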