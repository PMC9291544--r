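## Calendar helper: years for Date vectors, or a 365-day model calendar for
## plain day indices (day 1 belongs to year 1).
.mhw_years <- function(dates) {
  if (inherits(dates, "Date")) {
    as.integer(format(dates, "%Y"))
  } else {
    as.integer((as.numeric(dates) - 1) %/% 365 + 1)
  }
}

#' Percentile threshold of a baseline SST distribution
#'
#' Computes the empirical percentile (linear-interpolation estimator,
#' `quantile(type = 7)`) of all daily SSTs inside the baseline span. A marine
#' heatwave is a run of days exceeding this threshold; thresholding against
#' the whole pre-industrial distribution (rather than a day-of-year
#' climatology) treats any exceedance of historically extreme temperatures as
#' an event regardless of season. A day-of-year climatology mode is available
#' for comparison.
#'
#' @param sst Daily sea surface temperatures (degrees C).
#' @param dates Matching dates (`Date` or day indices); only needed for
#'   `baseline` given as a range or for `climatology = TRUE`.
#' @param baseline Either a logical/integer index into `sst`, or a
#'   length-2 range of `dates` (inclusive) marking the pre-industrial
#'   control segment. Default: all days.
#' @param probs Percentile(s) in (0, 100), typically 90 or 99.
#' @param climatology If `TRUE`, return a per-day threshold from a
#'   day-of-year climatology (window of `window` days around each
#'   day-of-year) instead of a single pooled value.
#' @param window Day-of-year window width for `climatology = TRUE`.
#' @return A single threshold per percentile (named vector), or with
#'   `climatology = TRUE` a matrix of per-day thresholds (days x percentiles).
#' @export
#' @examples
#' mhw_threshold(1:100, probs = 90) # 90.1 under linear interpolation
mhw_threshold <- function(sst, dates = NULL, baseline = NULL, probs = 90,
                          climatology = FALSE, window = 11) {
  stopifnot(all(probs > 0 & probs < 100))
  idx <- if (is.null(baseline)) {
    rep(TRUE, length(sst))
  } else if (is.logical(baseline) || (is.numeric(baseline) && length(baseline) != 2)) {
    baseline
  } else {
    if (is.null(dates)) .fail("baseline given as a range needs `dates`")
    dates >= baseline[1] & dates <= baseline[2]
  }
  base <- sst[idx]
  base <- base[is.finite(base)]
  if (!length(base)) .fail("empty baseline")
  if (!climatology) {
    q <- quantile(base, probs / 100, type = 7, names = FALSE)
    return(setNames(q, paste0("p", probs)))
  }
  if (is.null(dates)) .fail("climatology mode needs `dates`")
  doy_all <- if (inherits(dates, "Date")) {
    as.integer(format(dates, "%j"))
  } else {
    as.integer((as.numeric(dates) - 1) %% 365 + 1)
  }
  doy_base <- doy_all[idx][is.finite(sst[idx])]
  half <- window %/% 2
  per_doy <- vapply(1:366, function(d) {
    sel <- (abs(doy_base - d) <= half) | (abs(doy_base - d) >= 365 - half)
    if (!any(sel)) return(rep(NA_real_, length(probs)))
    quantile(base[sel], probs / 100, type = 7, names = FALSE)
  }, numeric(length(probs)))
  out <- t(matrix(per_doy, nrow = length(probs)))[doy_all, , drop = FALSE]
  colnames(out) <- paste0("p", probs)
  out
}

#' Detect marine heatwave events
#'
#' Finds maximal runs of consecutive days with `sst > threshold` of length at
#' least `min_duration`. Runs separated by any sub-threshold day are separate
#' events (no gap-joining). Each event reports its duration and maximum
#' intensity, the largest SST anomaly above the threshold.
#'
#' @param dates Daily dates (`Date` or day indices), strictly increasing.
#' @param sst Daily SSTs (degrees C), same length as `dates`.
#' @param threshold Scalar threshold, or a per-day vector (climatology mode).
#' @param min_duration Minimum event length in days (default 1: every
#'   exceedance day counts; the conventional 5-day rule is available by
#'   setting 5).
#' @return A data frame of class `mhw_events`: `start`, `end`,
#'   `duration_days`, `max_intensity_C`, `year_start`.
#' @export
mhw_events <- function(dates, sst, threshold, min_duration = 1) {
  stopifnot(length(dates) == length(sst), min_duration >= 1,
            all(is.finite(threshold)))
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0)) {
    .fail("dates must be strictly increasing")
  }
  exceed <- sst > threshold
  exceed[is.na(exceed)] <- FALSE
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  anomaly <- sst - threshold
  rows <- lapply(which(keep), function(i) {
    span <- starts[i]:ends[i]
    data.frame(start = dates[starts[i]], end = dates[ends[i]],
               duration_days = r$lengths[i],
               max_intensity_C = max(anomaly[span]),
               year_start = .mhw_years(dates[starts[i]]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(start = dates[0], end = dates[0],
               duration_days = integer(0), max_intensity_C = numeric(0),
               year_start = integer(0))
  }
  rownames(out) <- NULL
  class(out) <- c("mhw_events", "data.frame")
  out
}

#' Annual marine heatwave statistics
#'
#' Summarises detected events per calendar year: the maximum event intensity,
#' the mean event duration, and the total number of event days. Event-level
#' statistics (intensity, duration) are attributed to the year the event
#' starts in; day counts are attributed to the year of each constituent day,
#' so an event crossing a year boundary contributes days to both years.
#' Years without events report `n_mhw_days = 0` and `NA` intensity/duration.
#'
#' @param dates,sst,threshold,min_duration As in [mhw_events()].
#' @param events Optionally, precomputed [mhw_events()] output for the same
#'   series (recomputed when omitted).
#' @return A data frame of class `mhw_annual`: `year`,
#'   `max_annual_intensity_C`, `mean_annual_duration_days`, `n_mhw_days`.
#' @export
mhw_annual_stats <- function(dates, sst, threshold, min_duration = 1,
                             events = NULL) {
  if (is.null(events)) {
    events <- mhw_events(dates, sst, threshold, min_duration)
  }
  years_all <- .mhw_years(dates)
  years <- sort(unique(years_all))
  ## day-level attribution of event days
  day_in_event <- rep(FALSE, length(dates))
  if (nrow(events)) {
    num_dates <- as.numeric(dates)
    for (i in seq_len(nrow(events))) {
      day_in_event[num_dates >= as.numeric(events$start[i]) &
                     num_dates <= as.numeric(events$end[i])] <- TRUE
    }
  }
  rows <- lapply(years, function(y) {
    ev <- events[events$year_start == y, , drop = FALSE]
    data.frame(
      year = y,
      max_annual_intensity_C = if (nrow(ev)) max(ev$max_intensity_C) else NA_real_,
      mean_annual_duration_days = if (nrow(ev)) mean(ev$duration_days) else NA_real_,
      n_mhw_days = sum(day_in_event & years_all == y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mhw_annual", "data.frame")
  out
}

#' Multi-model envelope of annual MHW statistics
#'
#' Combines annual statistics from several climate models into per-year
#' multi-model mean, minimum and maximum — the summary used to draw a
#' central trajectory with a min/max plume.
#'
#' @param stats A data frame of stacked [mhw_annual_stats()] outputs with an
#'   added `model_id` column, or a named list of per-model `mhw_annual`
#'   tables.
#' @param cols Statistic columns to summarise.
#' @return A data frame with `year` and, for each statistic, `<col>_mean`,
#'   `<col>_min`, `<col>_max` across models.
#' @export
mhw_envelope <- function(stats,
                         cols = c("max_annual_intensity_C",
                                  "mean_annual_duration_days", "n_mhw_days")) {
  if (is.list(stats) && !is.data.frame(stats)) {
    ids <- names(stats)
    if (is.null(ids)) ids <- as.character(seq_along(stats))
    stats <- do.call(rbind, Map(function(df, id) {
      df <- as.data.frame(df)
      df$model_id <- id
      df
    }, stats, ids))
  }
  if (!nrow(stats)) .fail("no annual statistics supplied")
  years <- sort(unique(stats$year))
  out <- data.frame(year = years)
  for (cl in cols) {
    vals <- split(stats[[cl]], stats$year)
    agg <- function(f) vapply(vals, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) f(v) else NA_real_
    }, numeric(1))
    out[[paste0(cl, "_mean")]] <- unname(agg(mean)[as.character(years)])
    out[[paste0(cl, "_min")]] <- unname(agg(min)[as.character(years)])
    out[[paste0(cl, "_max")]] <- unname(agg(max)[as.character(years)])
  }
  out
}

#' Read a daily SST series from CSV
#'
#' Expects columns `date`, `sst` and optionally `model_id`; `date` is parsed
#' as ISO `Date` when possible, otherwise kept as a numeric day index on a
#' 365-day model calendar.
#'
#' @param path CSV path.
#' @return A data frame with `date`, `sst`, `model_id`.
#' @export
read_sst <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "sst") %in% names(df))) {
    .fail("SST file needs columns 'date' and 'sst'")
  }
  if (!"model_id" %in% names(df)) df$model_id <- "model1"
  if (is.character(df$date)) {
    parsed <- as.Date(df$date)
    if (!anyNA(parsed)) df$date <- parsed else .fail("unparseable dates")
  }
  df
}
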