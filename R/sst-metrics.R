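#' @noRd
validate_sst_series <- function(series) {
  if (isTRUE(attr(series, "sst_validated"))) return(series)
  if (!is.data.frame(series) || !all(c("date", "sst_c") %in% names(series)))
    stop("an SST series is a data frame with columns `date` and `sst_c`")
  series$date <- as.Date(series$date)
  series <- series[order(series$date), , drop = FALSE]
  if (anyDuplicated(series$date))
    stop("SST series has duplicated dates")
  if (any(!is.finite(series$sst_c)))
    stop("SST series has non-finite values")
  if (any(series$sst_c < -3 | series$sst_c > 45))
    stop("SST values outside the plausible [-3, 45] deg C range")
  attr(series, "sst_validated") <- TRUE
  series
}

#' Day-of-year SST climatology over a baseline period
#'
#' For each day of a fixed 365-slot year (Feb 29 pooled with Feb 28), the
#' climatological mean and upper percentile are computed from all baseline
#' values whose day-of-year falls in a centred window, wrapping across the
#' year boundary.
#'
#' @param series Daily SST data frame (`date`, `sst_c`).
#' @param baseline_years Length-2 inclusive span of baseline years.
#' @param window_days Odd width (days) of the centred pooling window.
#' @param percentile Upper percentile (default 90) used as the heatwave
#'   threshold.
#' @return An object of class `kelp_climatology`: a list with
#'   `mean_by_doy` and `p90_by_doy` (length-365 numeric vectors),
#'   `baseline_years`, `window_days`, `percentile`.
#' @export
compute_climatology <- function(series, baseline_years, window_days = 11,
                                percentile = 90) {
  if (window_days %% 2 != 1) stop("`window_days` must be odd")
  if (length(baseline_years) != 2L || baseline_years[2] < baseline_years[1])
    stop("`baseline_years` must be an inclusive c(first, last) span")
  series <- validate_sst_series(series)
  yr <- date_year(series$date)
  keep <- yr >= baseline_years[1] & yr <= baseline_years[2]
  if (!any(keep))
    stop("SST series does not intersect the baseline period ",
         baseline_years[1], "-", baseline_years[2])
  doy <- doy365(series$date[keep])
  sst <- series$sst_c[keep]
  vals_by_doy <- split(sst, factor(doy, levels = 1:365))
  half <- window_days %/% 2
  mean_by_doy <- p_by_doy <- numeric(365)
  for (d in 1:365) {
    win <- ((d - half):(d + half) - 1L) %% 365L + 1L
    v <- unlist(vals_by_doy[win], use.names = FALSE)
    if (length(v) == 0)
      stop("no baseline data for day-of-year ", d,
           "; the series must cover at least one full baseline year")
    mean_by_doy[d] <- mean(v)
    p_by_doy[d] <- stats::quantile(v, percentile / 100, names = FALSE)
  }
  structure(list(baseline_years = as.integer(round(baseline_years)),
                 window_days = as.integer(window_days),
                 percentile = percentile,
                 mean_by_doy = mean_by_doy, p90_by_doy = p_by_doy),
            class = "kelp_climatology")
}

#' Climatological values for a vector of dates
#'
#' @param clim A [compute_climatology()] result.
#' @param dates Dates to look up (Feb 29 maps to the Feb 28 slot).
#' @param what `"mean"` or `"p90"`.
#' @return Numeric vector of climatological SST (deg C).
#' @export
climatology_at <- function(clim, dates, what = c("mean", "p90")) {
  stopifnot(inherits(clim, "kelp_climatology"))
  what <- match.arg(what)
  v <- if (what == "mean") clim$mean_by_doy else clim$p90_by_doy
  v[doy365(as.Date(dates))]
}

#' Extract one warm season from a daily SST series
#'
#' The warm season of `season_year` runs 1 December of the previous year
#' through 30 April (151 days, 152 when February has 29 days), labelled by
#' the year containing its January.
#'
#' @param series Daily SST data frame.
#' @param season_year Integer season label.
#' @param max_missing Maximum tolerated missing days (default 5).
#' @return The season's rows of `series`, with attribute `season_year`.
#' @export
warm_season_slice <- function(series, season_year, max_missing = 5) {
  series <- validate_sst_series(series)
  d0 <- season_start(season_year)
  d1 <- season_end(season_year)
  n_expected <- as.integer(d1 - d0) + 1L
  dn <- as.numeric(series$date)
  out <- series[dn >= as.numeric(d0) & dn <= as.numeric(d1), , drop = FALSE]
  n_missing <- n_expected - nrow(out)
  if (n_missing > max_missing)
    stop("warm season ", season_year, " (Dec ", season_year - 1,
         "-Apr ", season_year, ") is missing ", n_missing,
         " of its ", n_expected, " days")
  attr(out, "season_year") <- as.integer(season_year)
  out
}

#' Warm-season temperature-extreme metrics
#'
#' Summarises one warm season relative to a climatology:
#' \describe{
#'   \item{mean_sst}{mean daily SST over the season (the "absolute
#'     temperature" metric, deg C);}
#'   \item{max_intensity}{largest daily anomaly above the climatological
#'     mean (deg C);}
#'   \item{cum_intensity}{sum of positive daily anomalies (deg C days),
#'     integrated over the whole season;}
#'   \item{tendency}{largest least-squares warming rate over any window of
#'     `tendency_window_days` consecutive days (deg C/day; negative
#'     maxima are reported as 0);}
#'   \item{max_monthly_sst}{warmest calendar-month mean SST (deg C).}
#' }
#'
#' @param series Daily SST data frame.
#' @param clim A [compute_climatology()] result.
#' @param season_year Integer season label.
#' @param tendency_window_days Window length for the tendency metric.
#' @param anomaly_ref Reference for anomalies: the climatological
#'   `"mean"` (default) or the `"p90"` threshold.
#' @return One-row data frame with columns `season_year`, `n_days`,
#'   `mean_sst`, `max_intensity`, `cum_intensity`, `tendency`,
#'   `max_monthly_sst`.
#' @export
warm_season_metrics <- function(series, clim, season_year,
                                tendency_window_days = 30,
                                anomaly_ref = c("mean", "p90")) {
  anomaly_ref <- match.arg(anomaly_ref)
  slice <- warm_season_slice(series, season_year)
  ref <- climatology_at(clim, slice$date,
                        what = if (anomaly_ref == "mean") "mean" else "p90")
  anom <- slice$sst_c - ref
  w <- tendency_window_days
  n <- nrow(slice)
  tendency <- 0
  if (n >= w) {
    day <- as.numeric(slice$date)
    slopes <- vapply(seq_len(n - w + 1), function(j) {
      x <- day[j:(j + w - 1)]; y <- slice$sst_c[j:(j + w - 1)]
      xc <- x - mean(x)
      sum(xc * y) / sum(xc^2)
    }, numeric(1))
    tendency <- max(0, max(slopes))
  }
  mon <- date_month(slice$date)
  monthly_means <- tapply(slice$sst_c, mon, mean)
  data.frame(season_year = as.integer(season_year), n_days = n,
             mean_sst = mean(slice$sst_c),
             max_intensity = max(anom),
             cum_intensity = sum(pmax(anom, 0)),
             tendency = tendency,
             max_monthly_sst = max(monthly_means))
}

#' Warm-season metrics for a run of seasons
#'
#' @param series Daily SST data frame.
#' @param clim A [compute_climatology()] result.
#' @param season_years Integer vector of season labels.
#' @param location Location label attached to every row.
#' @param ... Passed to [warm_season_metrics()].
#' @return Data frame with one row per season, first column `location`.
#' @export
warm_season_metrics_table <- function(series, clim, season_years,
                                      location = attr(series, "location_id"),
                                      ...) {
  rows <- lapply(season_years, function(y)
    warm_season_metrics(series, clim, y, ...))
  out <- do.call(rbind, rows)
  cbind(location = if (is.null(location)) NA_character_ else location, out)
}

#' Detect discrete marine heatwave events
#'
#' Maximal runs of days with SST above the seasonally varying percentile
#' threshold, lasting at least `min_duration` days; qualifying runs
#' separated by at most `max_gap` below-threshold days are merged into one
#' event. The series is assumed contiguous (daily) over the detection
#' span.
#'
#' @param series Daily SST data frame.
#' @param clim A [compute_climatology()] result (supplies the threshold).
#' @param min_duration Minimum run length in days (default 5).
#' @param max_gap Maximum below-threshold gap merged across (default 2).
#' @return Data frame with one row per event: `start_date`, `end_date`,
#'   `duration`, `peak_anomaly` (deg C above the climatological mean),
#'   `onset_rate` (deg C/day from start to peak; 0 when the peak is the
#'   first day). Zero rows when no event occurs.
#' @export
detect_mhw_events <- function(series, clim, min_duration = 5, max_gap = 2) {
  series <- validate_sst_series(series)
  thr <- climatology_at(clim, series$date, what = "p90")
  exceed <- series$sst_c > thr
  empty <- data.frame(start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      duration = integer(0), peak_anomaly = numeric(0),
                      onset_rate = numeric(0))
  if (!any(exceed)) return(empty)
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1L >= min_duration, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  anom <- series$sst_c - climatology_at(clim, series$date, what = "mean")
  do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    i0 <- merged$start[i]; i1 <- merged$end[i]
    seg <- i0:i1
    peak <- seg[which.max(series$sst_c[seg])]
    days_to_peak <- as.numeric(series$date[peak] - series$date[i0])
    data.frame(start_date = series$date[i0], end_date = series$date[i1],
               duration = as.integer(series$date[i1] - series$date[i0] + 1),
               peak_anomaly = max(anom[seg]),
               onset_rate = if (days_to_peak > 0)
                 (series$sst_c[peak] - series$sst_c[i0]) / days_to_peak
               else 0)
  }))
}
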