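#' Configuration for one synthetic kelp population
#'
#' Parameters of the generating model for annual canopy-cover surveys at
#' one location. Year-to-year cover change at site s in survey year y is
#'
#'   delta_{s,y} = true_slope * (T_summer(y) - clim_summer_mean) + u_s + eps_{s,y}
#'
#' with site random intercepts `u_s ~ N(0, site_sd^2)`, residuals
#' `eps ~ N(0, resid_sd^2)`, and cover clipped to `[0, 100]` (clipped
#' surveys are flagged). `T_summer(y)` is the mean SST of the warm season
#' (1 Dec y-1 .. 30 Apr y), and `clim_summer_mean` anchors the zero of
#' expected change.
#'
#' @param name Location label.
#' @param range_position One of `"warm_edge"`, `"central"`, `"cool_edge"`.
#' @param clim_summer_mean Warm-season climatological mean SST (deg C): the
#'   temperature at which expected cover change is zero.
#' @param true_slope Cover change per deg C of warm-season mean SST
#'   (percentage points per deg C; negative = decline with warming).
#' @param n_sites Number of survey sites (>= 1).
#' @param site_sd SD of site random intercepts (percentage points), >= 0.
#' @param resid_sd SD of residual change noise (percentage points), >= 0.
#' @param initial_cover Cover at the first survey (%), in `[0, 100]`.
#' @param survey_month Calendar month (1-12) of the annual survey.
#' @param years Length-2 inclusive span of survey years.
#' @param seed Integer seed; site intercepts and residuals are drawn from
#'   independent per-site sub-streams derived from it, so the output does
#'   not depend on iteration order.
#' @param sst Optional [sst_config()] for this location's SST forcing.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(name, range_position, clim_summer_mean,
                              true_slope, n_sites, site_sd = 0, resid_sd = 0,
                              initial_cover = 50, survey_month = 5,
                              years, seed = 1L, sst = NULL) {
  range_position <- match.arg(range_position, c("warm_edge", "central", "cool_edge"))
  if (!is_scalar_number(n_sites) || n_sites < 1) stop("`n_sites` must be >= 1")
  if (!is_scalar_number(site_sd) || site_sd < 0) stop("`site_sd` must be >= 0")
  if (!is_scalar_number(resid_sd) || resid_sd < 0) stop("`resid_sd` must be >= 0")
  if (!is_scalar_number(initial_cover) || initial_cover < 0 || initial_cover > 100)
    stop("`initial_cover` must lie in [0, 100]")
  if (!is_scalar_number(survey_month) || survey_month < 1 || survey_month > 12)
    stop("`survey_month` must be a month number")
  if (length(years) != 2L || years[2] <= years[1])
    stop("`years` must span at least two survey years")
  structure(
    list(name = name, range_position = range_position,
         clim_summer_mean = clim_summer_mean, true_slope = true_slope,
         n_sites = as.integer(n_sites), site_sd = site_sd,
         resid_sd = resid_sd, initial_cover = initial_cover,
         survey_month = as.integer(survey_month),
         years = as.integer(round(years)), seed = as.integer(seed),
         sst = sst),
    class = "population_config")
}

#' Expected warm-season mean SST of an SST configuration
#'
#' The climatological anchor implied by an [sst_config()]: the mean of
#' warm-season (Dec-Apr) mean SST over the baseline seasons of the
#' deterministic part of the series (seasonal cycle plus trend; noise and
#' injected events excluded). This is the natural zero-change anchor for
#' the survey generating model.
#'
#' @param sst_cfg An [sst_config()].
#' @param baseline_years Length-2 inclusive baseline span; defaults to
#'   the configuration's own span.
#' @return Warm-season climatological mean SST (deg C).
#' @export
expected_warm_season_mean <- function(sst_cfg, baseline_years = sst_cfg$years) {
  det_cfg <- sst_cfg
  det_cfg$noise_sd <- 0
  det_cfg$events <- list()
  # deterministic in the cycle/trend parameters: memoise
  key <- paste(det_cfg$mean_sst, det_cfg$seasonal_amplitude,
               det_cfg$phase_day, det_cfg$trend,
               det_cfg$years[1], det_cfg$years[2],
               baseline_years[1], baseline_years[2], sep = "|")
  hit <- .anchor_cache[[key]]
  if (!is.null(hit)) return(hit)
  sst <- generate_sst(det_cfg)
  seasons <- seq(max(baseline_years[1], sst_cfg$years[1]) + 1L,
                 min(baseline_years[2], sst_cfg$years[2]))
  sst <- validate_sst_series(sst)
  out <- mean(vapply(seasons, function(y) mean(warm_season_slice(sst, y)$sst_c),
                     numeric(1)))
  .anchor_cache[[key]] <- out
  out
}

#' Default population configurations along the range gradient
#'
#' Four locations spanning the species' southern-Australian range, with
#' response slopes of -1.7 (cool edge), -5.6 and -10.0 (central) and
#' -47.8 (warm edge) percentage points of cover per deg C, the latter a
#' single location-averaged series. Each carries a default SST
#' configuration whose injected warm events emulate the documented 2011
#' (west coast) and 2016 (Tasman Sea) marine heatwaves.
#'
#' @param seed Integer master seed; each population and its SST forcing
#'   receive distinct sub-seeds derived from it.
#' @param baseline_years Baseline span over which each population's
#'   climatological anchor is computed (see
#'   [expected_warm_season_mean()]).
#' @return Named list of [population_config()] objects
#'   (`maria_island`, `jervis_bay`, `jurien`, `kalbarri`).
#' @export
default_populations <- function(seed = 1L, baseline_years = c(1991, 2020)) {
  seed <- as.integer(seed)
  sub <- function(k) (seed * 131L + k) %% 2147483647L
  ssts <- list(
    maria_island = sst_config(
      mean_sst = 14.0, seasonal_amplitude = 3.4,
      ar1_coeff = 0.95, noise_sd = 0.35, trend = 0.02,
      events = list(list(start_date = "2016-01-10", duration_days = 50,
                         peak_anomaly = 1.5, shape = "triangular")),
      years = c(1991, 2023), seed = sub(11L), location_id = "maria_island"),
    jervis_bay = sst_config(
      mean_sst = 19.0, seasonal_amplitude = 3.4,
      ar1_coeff = 0.95, noise_sd = 0.35, trend = 0.02,
      events = list(list(start_date = "2019-01-05", duration_days = 40,
                         peak_anomaly = 1.2, shape = "triangular")),
      years = c(1991, 2023), seed = sub(12L), location_id = "jervis_bay"),
    jurien = sst_config(
      mean_sst = 20.4, seasonal_amplitude = 2.8,
      ar1_coeff = 0.95, noise_sd = 0.35, trend = 0.02,
      events = list(list(start_date = "2011-01-15", duration_days = 60,
                         peak_anomaly = 2.0, shape = "triangular"),
                    list(start_date = "1999-02-01", duration_days = 30,
                         peak_anomaly = 1.0, shape = "rect")),
      years = c(1991, 2023), seed = sub(13L), location_id = "jurien"),
    kalbarri = sst_config(
      mean_sst = 22.0, seasonal_amplitude = 2.7,
      ar1_coeff = 0.95, noise_sd = 0.35, trend = 0.02,
      events = list(list(start_date = "2011-01-10", duration_days = 60,
                         peak_anomaly = 1.5, shape = "rect")),
      years = c(1991, 2013), seed = sub(14L), location_id = "kalbarri"))
  anchor <- vapply(ssts, expected_warm_season_mean, numeric(1),
                   baseline_years = baseline_years)
  list(
    maria_island = population_config(
      name = "maria_island", range_position = "cool_edge",
      clim_summer_mean = anchor[["maria_island"]], true_slope = -1.7,
      n_sites = 10, site_sd = 2, resid_sd = 5, initial_cover = 60,
      survey_month = 5, years = c(1993, 2023), seed = sub(1L),
      sst = ssts$maria_island),
    jervis_bay = population_config(
      name = "jervis_bay", range_position = "central",
      clim_summer_mean = anchor[["jervis_bay"]], true_slope = -5.6,
      n_sites = 6, site_sd = 2, resid_sd = 5, initial_cover = 50,
      survey_month = 5, years = c(1993, 2023), seed = sub(2L),
      sst = ssts$jervis_bay),
    jurien = population_config(
      name = "jurien", range_position = "central",
      clim_summer_mean = anchor[["jurien"]], true_slope = -10.0,
      n_sites = 4, site_sd = 2, resid_sd = 5, initial_cover = 50,
      survey_month = 10, years = c(1993, 2023), seed = sub(3L),
      sst = ssts$jurien),
    kalbarri = population_config(
      name = "kalbarri", range_position = "warm_edge",
      clim_summer_mean = anchor[["kalbarri"]], true_slope = -47.8,
      n_sites = 1, site_sd = 0, resid_sd = 5, initial_cover = 50,
      survey_month = 12, years = c(2002, 2012), seed = sub(4L),
      sst = ssts$kalbarri))
}

#' Generate synthetic canopy-cover surveys
#'
#' Simulates one survey per site per year of each population's span,
#' evolving cover by the linear warm-season response model of
#' [population_config()] and clipping to `[0, 100]`. Surveys whose cover
#' was clipped are flagged (`clipped = TRUE`): the arriving change of a
#' clipped survey is boundary-distorted and can be excluded downstream.
#'
#' @param pops A [population_config()] or list of them.
#' @param sst_by_pop A daily SST data frame (as from [generate_sst()]) or a
#'   list of them, parallel to `pops`; defaults to generating each
#'   population's own `sst` configuration.
#' @return A data frame with columns `location`, `site`, `date`,
#'   `cover_pct`, `clipped`.
#' @export
generate_surveys <- function(pops, sst_by_pop = NULL) {
  if (inherits(pops, "population_config")) pops <- list(pops)
  if (!is.null(sst_by_pop) && is.data.frame(sst_by_pop))
    sst_by_pop <- list(sst_by_pop)
  out <- lapply(seq_along(pops), function(i) {
    sst <- if (is.null(sst_by_pop)) {
      if (is.null(pops[[i]]$sst))
        stop("no SST series supplied and population `", pops[[i]]$name,
             "` has no sst config")
      generate_sst(pops[[i]]$sst)
    } else sst_by_pop[[i]]
    generate_surveys_one(pops[[i]], sst)
  })
  do.call(rbind, out)
}

#' @noRd
generate_surveys_one <- function(pop, sst) {
  sst <- validate_sst_series(sst)
  years <- seq(pop$years[1], pop$years[2])
  seasons <- years[-1]
  t_summer <- vapply(seasons, function(y) {
    mean(warm_season_slice(sst, y)$sst_c)
  }, numeric(1))
  n_sites <- pop$n_sites
  u <- if (pop$site_sd > 0)
    withr::with_seed(pop$seed, stats::rnorm(n_sites, 0, pop$site_sd))
  else rep(0, n_sites)
  site_names <- sprintf("%s_site_%02d", pop$name, seq_len(n_sites))
  recs <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    eps <- if (pop$resid_sd > 0) {
      withr::with_seed((pop$seed + 7919L * s) %% 2147483647L,
                       stats::rnorm(length(seasons), 0, pop$resid_sd))
    } else rep(0, length(seasons))
    cover <- numeric(length(years))
    clipped <- logical(length(years))
    cover[1] <- pop$initial_cover
    for (k in seq_along(seasons)) {
      delta <- pop$true_slope * (t_summer[k] - pop$clim_summer_mean) +
        u[s] + eps[k]
      raw <- cover[k] + delta
      cover[k + 1] <- min(100, max(0, raw))
      clipped[k + 1] <- raw < 0 || raw > 100
    }
    recs[[s]] <- data.frame(
      location = pop$name, site = site_names[s],
      date = as.Date(sprintf("%d-%02d-15", years, pop$survey_month)),
      cover_pct = cover, clipped = clipped)
  }
  do.call(rbind, recs)
}
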