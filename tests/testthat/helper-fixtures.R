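# Shared fixtures, built in code at test time.

# Constant-temperature SST over a span of years.
constant_sst <- function(value = 15, years = c(2000, 2002)) {
  generate_sst(sst_config(mean_sst = value, seasonal_amplitude = 0,
                          years = years))
}

# A population with analytic behaviour: constant SST at `t_summer`,
# configurable anchor, no survey noise unless asked for.
toy_population <- function(true_slope = -10, anchor = 19, t_summer = 20,
                           n_sites = 1, site_sd = 0, resid_sd = 0,
                           initial_cover = 50, years = c(2000, 2005),
                           seed = 1) {
  sst <- sst_config(mean_sst = t_summer, seasonal_amplitude = 0,
                    years = c(years[1] - 1, years[2]), seed = seed)
  population_config(name = "toy", range_position = "central",
                    clim_summer_mean = anchor, true_slope = true_slope,
                    n_sites = n_sites, site_sd = site_sd,
                    resid_sd = resid_sd, initial_cover = initial_cover,
                    survey_month = 6, years = years, seed = seed, sst = sst)
}

# Analysis table for one default population at one seed: minimal route
# (seasonal mean SST only), used by recovery and diagnostics tests.
population_analysis_table <- function(pop) {
  sst <- generate_sst(pop$sst)
  surveys <- generate_surveys(pop, sst)
  pairs <- suppressMessages(pair_consecutive_surveys(surveys))
  seasons <- sort(unique(pairs$season_year))
  t_summer <- vapply(seasons, function(y)
    mean(warm_season_slice(sst, y)$sst_c), numeric(1))
  attach_metrics(pairs, data.frame(location = pop$name,
                                   season_year = seasons,
                                   mean_sst = t_summer))
}

# Independent day-by-day state machine for heatwave event detection,
# used as the brute-force oracle against detect_mhw_events().
brute_force_events <- function(sst, thr, dates, min_duration = 5,
                               max_gap = 2) {
  n <- length(sst)
  above <- sst > thr
  # collect maximal runs by explicit scan
  runs <- list(); start <- NA
  for (i in seq_len(n)) {
    if (above[i] && is.na(start)) start <- i
    if ((!above[i] || i == n) && !is.na(start)) {
      end <- if (above[i]) i else i - 1
      runs[[length(runs) + 1]] <- c(start, end)
      start <- NA
    }
  }
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_duration, runs)
  if (length(runs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= max_gap)
      merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  data.frame(start = vapply(merged, `[`, numeric(1), 1),
             end = vapply(merged, `[`, numeric(1), 2))
}
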