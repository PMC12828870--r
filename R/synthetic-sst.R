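#' Configuration for a synthetic daily SST series
#'
#' Describes one location's daily sea-surface temperature as a seasonal
#' cycle plus linear trend, AR(1) noise, and optional injected warm
#' anomalies ("events") that stand in for marine heatwaves.
#'
#' @param mean_sst Annual-mean SST (deg C).
#' @param seasonal_amplitude Amplitude of the seasonal cosine cycle (deg C).
#' @param phase_day Day-of-year of the seasonal peak (default 46, mid-February,
#'   a southern-hemisphere summer peak).
#' @param ar1_coeff Lag-1 autoregression coefficient of the daily noise,
#'   in `[0, 1)`.
#' @param noise_sd Standard deviation of the AR(1) innovations (deg C), >= 0.
#' @param trend Linear warming trend (deg C per year).
#' @param events List of injected warm anomalies, each a list with elements
#'   `start_date` (coercible to Date), `duration_days` (>= 1),
#'   `peak_anomaly` (deg C) and `shape` (`"rect"` or `"triangular"`).
#' @param years Length-2 integer vector: inclusive first and last calendar
#'   year of the series.
#' @param seed Integer seed; the series is deterministic given the seed.
#' @param location_id Optional label carried on the generated series.
#'
#' @return An object of class `sst_config`.
#' @seealso [generate_sst()]
#' @export
sst_config <- function(mean_sst, seasonal_amplitude = 0, phase_day = 46,
                       ar1_coeff = 0, noise_sd = 0, trend = 0,
                       events = list(), years, seed = 1L,
                       location_id = "synthetic") {
  stopifnot(is_scalar_number(mean_sst), is_scalar_number(seasonal_amplitude),
            is_scalar_number(phase_day), is_scalar_number(trend))
  if (!is_scalar_number(ar1_coeff) || ar1_coeff < 0 || ar1_coeff >= 1)
    stop("`ar1_coeff` must lie in [0, 1)")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  if (length(years) != 2L || any(!is.finite(years)) || years[2] < years[1])
    stop("`years` must be an inclusive, non-empty c(first, last) span")
  events <- lapply(events, function(ev) {
    ev$start_date <- as.Date(ev$start_date)
    if (is.null(ev$shape)) ev$shape <- "rect"
    ev$shape <- match.arg(ev$shape, c("rect", "triangular"))
    if (!is_scalar_number(ev$duration_days) || ev$duration_days < 1)
      stop("event `duration_days` must be >= 1")
    if (!is_scalar_number(ev$peak_anomaly)) stop("event `peak_anomaly` must be a number")
    ev
  })
  structure(
    list(mean_sst = mean_sst, seasonal_amplitude = seasonal_amplitude,
         phase_day = phase_day, ar1_coeff = ar1_coeff, noise_sd = noise_sd,
         trend = trend, events = events,
         years = as.integer(round(years)), seed = as.integer(seed),
         location_id = location_id),
    class = "sst_config")
}

#' Generate a synthetic daily SST series
#'
#' Produces one SST value per calendar day of the configured span:
#' `mean + amplitude * cos(2 * pi * (doy - phase_day) / 365.25)` plus a
#' linear trend, seeded AR(1) noise, and the anomaly profile of each
#' injected event. Rectangular events add `peak_anomaly` on every event
#' day; triangular events ramp linearly up to the peak at the event
#' midpoint and back down.
#'
#' @param config An [sst_config()].
#' @return A data frame with columns `date` (Date) and `sst_c` (deg C),
#'   one row per day, with the location label in attribute `location_id`.
#' @examples
#' cfg <- sst_config(mean_sst = 15, seasonal_amplitude = 3, years = c(2000, 2001))
#' sst <- generate_sst(cfg)
#' range(sst$sst_c)
#' @export
generate_sst <- function(config) {
  stopifnot(inherits(config, "sst_config"))
  y0 <- config$years[1]; y1 <- config$years[2]
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y1)), by = "day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  cycle <- config$mean_sst +
    config$seasonal_amplitude * cos(2 * pi * (doy - config$phase_day) / 365.25)
  trend <- config$trend * (seq_len(n) - 1) / 365.25
  noise <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed, {
      innov <- stats::rnorm(n, 0, config$noise_sd)
      as.numeric(stats::filter(innov, config$ar1_coeff, method = "recursive"))
    })
  } else rep(0, n)
  anom <- rep(0, n)
  for (ev in config$events) {
    idx <- match(seq(ev$start_date, by = "day", length.out = ev$duration_days),
                 dates)
    prof <- if (ev$shape == "rect") {
      rep(ev$peak_anomaly, ev$duration_days)
    } else {
      half <- (ev$duration_days + 1) / 2
      ev$peak_anomaly * (1 - abs(seq_len(ev$duration_days) - half) / half)
    }
    keep <- !is.na(idx)
    anom[idx[keep]] <- anom[idx[keep]] + prof[keep]
  }
  out <- data.frame(date = dates, sst_c = cycle + trend + noise + anom)
  attr(out, "location_id") <- config$location_id
  out
}
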