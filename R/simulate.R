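#' Simulate two-arm coral experiments with known ground truth
#'
#' Generates experiment records whose latent effect sizes are known exactly,
#' for end-to-end validation of the effect-size and meta-analysis stages.
#' The generator mirrors the structure of the published experimental corpus:
#' many studies, each contributing a few contrasts on one coral genus, with
#' control temperatures of 24-30 C, warming of +0.5 to +13 C, control pCO2
#' of 297-486 uatm and CO2 increments of +100 to +800 uatm.
#'
#' For each record the latent effect is
#' `true_effect = truth + u_study + w_genus` with independent normal study
#' and genus deviations on the effect scale, the treatment mean is
#' `control * exp(-true_effect * d(1/kT))` (warming) or
#' `control * exp(true_effect * dpCO2 / 100)` (CO2), and each arm reports the
#' sample mean/SD/n of `n` lognormal replicate observations with
#' coefficient of variation `noise_cv` (keeping outcomes positive, as log
#' ratios require). With `noise_cv = 0` the reported means are the latent
#' means exactly (SDs are 0), so the effect-size stage must recover the
#' latent effect to machine precision.
#'
#' @param n_studies Number of studies.
#' @param effects_per_study Contrasts contributed by each study.
#' @param n_genera Size of the genus pool (each study works on one genus).
#' @param arm_types Types to draw records from (`"warming"`, `"co2"`,
#'   `"both"`), sampled uniformly.
#' @param attributes Attribute labels to sample from.
#' @param true_E True activation energy (eV); scalar or named by attribute.
#' @param true_lnrr100 True log response ratio per +100 uatm; scalar or named
#'   by attribute.
#' @param control_T_range,warming_range,control_pco2_range,delta_pco2_range
#'   Uniform envelopes (degrees C / uatm) the drawn conditions stay inside.
#' @param noise_cv Lognormal coefficient of variation of replicate
#'   observations within an arm.
#' @param arm_n_range Range of per-arm sample sizes (inclusive).
#' @param sigma2_study,sigma2_genus Between-study / between-genus variance of
#'   the latent effect (effect-size scale), the heterogeneity the
#'   meta-analysis must recover.
#' @param control_mean_log_mu,control_mean_log_sd Lognormal parameters of the
#'   control-arm outcome scale.
#' @param seed Optional integer seed.
#' @return A list with `records` (a `coral_experiments` table) and `truth`, a
#'   data frame holding every latent draw (`true_effect`, `u_study`,
#'   `w_genus`, latent means and contrast geometry) plus `params`.
#' @export
sim_experiments <- function(n_studies = 40, effects_per_study = 3,
                            n_genera = 15, arm_types = c("warming", "co2"),
                            attributes = "survival",
                            true_E = 1.0, true_lnrr100 = -0.02,
                            control_T_range = c(24, 30),
                            warming_range = c(0.5, 13),
                            control_pco2_range = c(297, 486),
                            delta_pco2_range = c(100, 800),
                            noise_cv = 0.2, arm_n_range = c(4, 8),
                            sigma2_study = 0.05, sigma2_genus = 0.02,
                            control_mean_log_mu = log(10),
                            control_mean_log_sd = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_studies >= 1, effects_per_study >= 1, noise_cv >= 0,
            all(arm_types %in% c("warming", "co2", "both")))
  studies <- sprintf("study%03d", seq_len(n_studies))
  genera <- sprintf("genus%02d", seq_len(n_genera))
  study_genus <- sample(genera, n_studies, replace = TRUE)
  u_study <- rnorm(n_studies, 0, sqrt(sigma2_study))
  w_genus <- rnorm(n_genera, 0, sqrt(sigma2_genus))
  names(u_study) <- studies
  names(w_genus) <- genera

  get_truth <- function(tbl, attr) {
    if (is.null(names(tbl))) tbl[1] else unname(tbl[attr])
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  draw_arm <- function(mu, n) {
    if (noise_cv == 0) return(c(mean = mu, sd = 0))
    obs <- rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    c(mean = mean(obs), sd = sd(obs))
  }

  rec <- list()
  tru <- list()
  rid <- 0L
  for (i in seq_len(n_studies)) {
    for (j in seq_len(effects_per_study)) {
      rid <- rid + 1L
      arm <- sample(arm_types, 1)
      attr <- sample(attributes, 1)
      genus <- study_genus[i]
      t_c <- runif(1, control_T_range[1], control_T_range[2])
      p_c <- runif(1, control_pco2_range[1], control_pco2_range[2])
      if (arm %in% c("warming", "both")) {
        dT <- runif(1, warming_range[1], warming_range[2])
        t_t <- t_c + dT
        eff <- unname(get_truth(true_E, attr) + u_study[i] + w_genus[genus])
        d <- delta_inv_kT(t_c, t_t)
        ratio <- exp(-eff * d)
        kind <- "arrhenius_E"
      } else {
        t_t <- t_c
        eff <- unname(get_truth(true_lnrr100, attr) + u_study[i] +
                        w_genus[genus])
        kind <- "lnrr_co2"
      }
      if (arm %in% c("co2", "both")) {
        dp <- runif(1, delta_pco2_range[1], delta_pco2_range[2])
        p_t <- p_c + dp
        if (arm == "co2") ratio <- exp(eff * dp / 100)
      } else {
        p_t <- p_c
        dp <- 0
      }
      mu_c <- rlnorm(1, control_mean_log_mu, control_mean_log_sd)
      mu_t <- mu_c * ratio
      n_c <- sample(arm_n_range[1]:arm_n_range[2], 1)
      n_t <- sample(arm_n_range[1]:arm_n_range[2], 1)
      a_c <- draw_arm(mu_c, n_c)
      a_t <- draw_arm(mu_t, n_t)
      rec[[rid]] <- data.frame(
        study_id = studies[i], genus = genus, species = NA_character_,
        attribute = attr, arm_type = arm,
        control_mean = unname(a_c[1]), control_sd = unname(a_c[2]),
        control_n = n_c,
        treatment_mean = unname(a_t[1]), treatment_sd = unname(a_t[2]),
        treatment_n = n_t,
        t_control_C = t_c, t_treatment_C = t_t,
        pco2_control_uatm = p_c, pco2_treatment_uatm = p_t,
        duration_days = 22, stringsAsFactors = FALSE)
      tru[[rid]] <- data.frame(
        record = rid, study_id = studies[i], genus = genus, attribute = attr,
        arm_type = arm, kind = kind, true_effect = unname(eff),
        u_study = unname(u_study[i]), w_genus = unname(w_genus[genus]),
        control_mean_true = mu_c, treatment_mean_true = mu_t,
        delta_inv_kT = if (kind == "arrhenius_E") delta_inv_kT(t_c, t_t)
        else NA_real_,
        delta_pco2_uatm = if (dp > 0) dp else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  records <- experiment_records(do.call(rbind, rec))
  truth <- do.call(rbind, tru)
  rownames(truth) <- NULL
  list(records = records, truth = truth,
       params = list(n_studies = n_studies,
                     effects_per_study = effects_per_study,
                     n_genera = n_genera, noise_cv = noise_cv,
                     sigma2_study = sigma2_study,
                     sigma2_genus = sigma2_genus,
                     true_E = true_E, true_lnrr100 = true_lnrr100))
}

#' Simulate full-factorial quads with a known interaction
#'
#' Builds warming x CO2 quads around a multiplicative null: the latent arm
#' means are `control`, `control * warming_ratio`, `control * co2_ratio` and
#' `control * warming_ratio * co2_ratio * exp(interaction_magnitude)`, so
#' `interaction_magnitude = 0` is exactly additive on the multiplicative
#' scale. Observed arm means are the latent means perturbed by lognormal
#' mean-level noise with standard deviation matching the sampling noise of a
#' mean of `arm_n` replicates of coefficient of variation `noise_cv`
#' (`sdlog = sqrt(log(1 + noise_cv^2/arm_n))`); the reported arm SD is the
#' known replicate-level SD `reported_cv * latent mean`. Under this
#' construction the delta-method CI of the interaction is calibrated, which
#' is what the type-I validation of the classifier exercises.
#'
#' @param n_quads Number of quads.
#' @param warming_ratio,co2_ratio Latent individual multiplicative effects
#'   (values below 1 are declines).
#' @param interaction_magnitude Latent interaction on the log scale (0 =
#'   multiplicative null).
#' @param noise_cv Replicate-level coefficient of variation driving the
#'   mean-level noise.
#' @param reported_cv Replicate-level CV used for the reported arm SDs
#'   (defaults to `noise_cv`; set it positive with `noise_cv = 0` to obtain
#'   noiseless means with non-degenerate SDs).
#' @param arm_n Sample size per arm.
#' @param n_genera Genus pool size for the labels.
#' @param attributes Attribute labels to sample from.
#' @param control_mean_log_mu,control_mean_log_sd Scale of the control arm.
#' @param seed Optional integer seed.
#' @return A list with `quads` (a `coral_quads` table) and `truth` (latent
#'   arm means and the true interaction per quad) plus `params`.
#' @export
sim_factorial <- function(n_quads = 100, warming_ratio = 0.8,
                          co2_ratio = 0.9, interaction_magnitude = 0,
                          noise_cv = 0.2, reported_cv = noise_cv, arm_n = 4,
                          n_genera = 15, attributes = "calcification",
                          control_mean_log_mu = log(10),
                          control_mean_log_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_quads >= 1, arm_n >= 2, noise_cv >= 0, reported_cv >= 0)
  genera <- sprintf("genus%02d", seq_len(n_genera))
  sdlog <- sqrt(log(1 + noise_cv^2 / arm_n))
  qs <- list()
  tru <- list()
  for (i in seq_len(n_quads)) {
    mu0 <- rlnorm(1, control_mean_log_mu, control_mean_log_sd)
    mu <- c(control = mu0,
            warming = mu0 * warming_ratio,
            co2 = mu0 * co2_ratio,
            both = mu0 * warming_ratio * co2_ratio * exp(interaction_magnitude))
    obs <- if (noise_cv == 0) mu else {
      mu * exp(rnorm(4, -sdlog^2 / 2, sdlog))
    }
    sds <- reported_cv * mu
    genus <- sample(genera, 1)
    attr <- sample(attributes, 1)
    qs[[i]] <- data.frame(
      study_id = sprintf("study%03d", i), genus = genus, attribute = attr,
      mean_control = obs["control"], mean_warming = obs["warming"],
      mean_co2 = obs["co2"], mean_both = obs["both"],
      sd_control = sds["control"], sd_warming = sds["warming"],
      sd_co2 = sds["co2"], sd_both = sds["both"],
      n_control = arm_n, n_warming = arm_n, n_co2 = arm_n, n_both = arm_n,
      t_control_C = 27, t_treatment_C = 30,
      pco2_control_uatm = 400, pco2_treatment_uatm = 800,
      stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(
      quad = i, interaction_magnitude = interaction_magnitude,
      mean_control_true = mu[["control"]], mean_warming_true = mu[["warming"]],
      mean_co2_true = mu[["co2"]], mean_both_true = mu[["both"]],
      stringsAsFactors = FALSE)
  }
  quads <- factorial_quads(do.call(rbind, qs))
  truth <- do.call(rbind, tru)
  rownames(truth) <- NULL
  list(quads = quads, truth = truth,
       params = list(n_quads = n_quads, warming_ratio = warming_ratio,
                     co2_ratio = co2_ratio,
                     interaction_magnitude = interaction_magnitude,
                     noise_cv = noise_cv, reported_cv = reported_cv,
                     arm_n = arm_n))
}

#' Simulate a daily SST series with injected heatwave blocks
#'
#' Builds `years` x 365 days of sea surface temperature on a 365-day model
#' calendar: a constant mean, sinusoidal seasonality, a linear trend, AR(1)
#' noise (stationary initialisation), and additive rectangular event blocks
#' of given start day, duration and amplitude. The first `baseline_years`
#' years act as the pre-industrial control segment used to set percentile
#' thresholds.
#'
#' @param years Total length in years (365-day years).
#' @param baseline_years Years at the start forming the baseline span.
#' @param mean_C Long-term mean (degrees C).
#' @param seasonal_amplitude_C Amplitude of the annual sine cycle.
#' @param ar1 AR(1) coefficient of the noise, in `[0, 1)`.
#' @param noise_sd_C Innovation standard deviation of the AR(1) noise; 0
#'   gives a deterministic series.
#' @param trend_C_per_decade Linear warming trend.
#' @param events Optional data frame of injected blocks with columns
#'   `start` (day index), `duration_days`, `amplitude_C`.
#' @param model_id Label attached to the series.
#' @param seed Optional integer seed.
#' @return A list with `data` (data frame `date` (day index), `sst`,
#'   `model_id`), `baseline` (logical index of baseline days) and `truth`
#'   (the injected `events` and generator parameters).
#' @export
sim_sst <- function(years = 50, baseline_years = 20, mean_C = 27,
                    seasonal_amplitude_C = 2, ar1 = 0.7, noise_sd_C = 0.3,
                    trend_C_per_decade = 0, events = NULL,
                    model_id = "model1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(years >= 1, baseline_years >= 1, baseline_years <= years,
            ar1 >= 0, ar1 < 1, noise_sd_C >= 0)
  n <- years * 365L
  day <- seq_len(n)
  doy <- (day - 1) %% 365 + 1
  sst <- mean_C + seasonal_amplitude_C * sin(2 * pi * (doy - 1) / 365) +
    trend_C_per_decade * (day - 1) / 3650
  if (noise_sd_C > 0) {
    eps <- numeric(n)
    eps[1] <- rnorm(1, 0, noise_sd_C / sqrt(1 - ar1^2))
    innov <- rnorm(n - 1, 0, noise_sd_C)
    for (t in 2:n) eps[t] <- ar1 * eps[t - 1] + innov[t - 1]
    sst <- sst + eps
  }
  if (!is.null(events) && nrow(events)) {
    stopifnot(all(c("start", "duration_days", "amplitude_C") %in%
                    names(events)),
              all(events$duration_days >= 1))
    for (i in seq_len(nrow(events))) {
      span <- events$start[i]:(events$start[i] + events$duration_days[i] - 1)
      span <- span[span <= n]
      sst[span] <- sst[span] + events$amplitude_C[i]
    }
  }
  list(data = data.frame(date = day, sst = sst, model_id = model_id,
                         stringsAsFactors = FALSE),
       baseline = day <= baseline_years * 365L,
       truth = list(events = events,
                    params = list(years = years,
                                  baseline_years = baseline_years,
                                  mean_C = mean_C,
                                  seasonal_amplitude_C = seasonal_amplitude_C,
                                  ar1 = ar1, noise_sd_C = noise_sd_C,
                                  trend_C_per_decade = trend_C_per_decade)))
}
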