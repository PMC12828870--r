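#' Configuration of an end-to-end synthetic run
#'
#' Bundles the population configurations, TPC configurations, baseline
#' span, metric list, and the global seed from which every generator
#' sub-seed is derived.
#'
#' @param populations Named list of [population_config()] objects
#'   (default [default_populations()] under `seed`).
#' @param tpc_configs Named list of [tpc_gen_config()] objects.
#' @param baseline_years Climatology baseline span (default 1991-2020).
#' @param metrics Metric columns to fit slopes against.
#' @param month_rules Survey-month rules passed to
#'   [filter_survey_months()].
#' @param seed Global integer seed.
#' @return An object of class `kelp_run_config`.
#' @export
kelp_run_config <- function(populations = default_populations(seed),
                            tpc_configs = default_tpc_configs(seed),
                            baseline_years = c(1991, 2020),
                            metrics = c("mean_sst", "max_intensity",
                                        "cum_intensity", "tendency"),
                            month_rules = list(maria_island = 3:5),
                            seed = 1L) {
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("population names must be unique")
  structure(list(populations = populations, tpc_configs = tpc_configs,
                 baseline_years = baseline_years, metrics = metrics,
                 month_rules = month_rules, seed = as.integer(seed)),
            class = "kelp_run_config")
}

#' @noRd
pipeline_stage <- function(stage, pop_name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", stage, "` failed for `", pop_name, "`: ",
         conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end synthetic experiment
#'
#' For each population: generate its SST forcing, compute the baseline
#' climatology and per-season warm-season metrics, generate surveys,
#' filter and pair them, attach metrics, and fit a response slope per
#' metric plus the zero-crossing threshold (absolute-temperature metric)
#' and residual lag-1 diagnostics. Finishes with the cross-population
#' volatility ordering and the thermal-performance fits. Fully
#' deterministic given the configuration's seed.
#'
#' @param config A [kelp_run_config()].
#' @return List of class `kelp_run_report` with elements `populations`
#'   (per population: `metrics_table`, `analysis_table`, `fits`,
#'   `threshold`, `autocorr`, `n_pairs_dropped`), `volatility`
#'   (see [volatility_report()]), `tpc` (per config: fit and limits),
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kelp_run_config"))
  pops <- config$populations
  results <- lapply(pops, function(pop) {
    nm <- pop$name
    sst <- pipeline_stage("generate_sst", nm, generate_sst(pop$sst))
    clim <- pipeline_stage("compute_climatology", nm, {
      bl <- config$baseline_years
      bl[1] <- max(bl[1], pop$sst$years[1])
      bl[2] <- min(bl[2], pop$sst$years[2])
      compute_climatology(sst, bl)
    })
    surveys <- pipeline_stage("generate_surveys", nm,
                              generate_surveys(pop, sst))
    surveys <- filter_survey_months(surveys, config$month_rules)
    pairs <- pipeline_stage("pair_surveys", nm,
                            suppressMessages(pair_consecutive_surveys(surveys)))
    seasons <- sort(unique(pairs$season_year))
    mt <- pipeline_stage("warm_season_metrics", nm,
                         warm_season_metrics_table(sst, clim, seasons,
                                                   location = nm))
    tab <- pipeline_stage("attach_metrics", nm, attach_metrics(pairs, mt))
    fits <- lapply(config$metrics, function(m)
      pipeline_stage(paste0("fit_", m), nm, fit_location_slope(tab, m)))
    names(fits) <- config$metrics
    threshold <- if ("mean_sst" %in% config$metrics)
      pipeline_stage("zero_crossing", nm,
                     zero_crossing_threshold(fits$mean_sst,
                                             pop$clim_summer_mean))
    else NULL
    autocorr <- if ("mean_sst" %in% config$metrics)
      suppressWarnings(residual_lag1_autocorr(fits$mean_sst)) else NULL
    list(metrics_table = mt, analysis_table = tab, fits = fits,
         threshold = threshold, autocorr = autocorr,
         n_pairs_dropped = attr(pairs, "n_dropped"))
  })
  names(results) <- vapply(pops, `[[`, character(1), "name")
  vol <- if ("mean_sst" %in% config$metrics) {
    volatility_report(lapply(results, function(r) r$fits$mean_sst),
                      anchors = vapply(pops, `[[`, numeric(1),
                                       "clim_summer_mean"))
  } else NULL
  tpc <- lapply(config$tpc_configs, function(tc) {
    obs <- generate_tpc_observations(tc)
    fit <- fit_tpc(obs, seed = config$seed)
    list(fit = fit, topt_hat = fit$topt_hat, ctmax_hat = fit$ctmax_hat)
  })
  structure(list(populations = results, volatility = vol, tpc = tpc,
                 config = config),
            class = "kelp_run_report")
}

#' Rank populations by response-slope magnitude
#'
#' Orders the per-population absolute-temperature slope fits by `|slope|`
#' (descending — most volatile first), breaking ties by name, and lists
#' each fitted zero-crossing threshold beside its configured
#' climatological anchor.
#'
#' @param fits Named list of [fit_location_slope()] results (one per
#'   population, absolute-temperature metric).
#' @param anchors Optional named numeric vector of climatological
#'   anchors (deg C), parallel to `fits`.
#' @return Data frame ordered by rank: `location`, `slope`, `slope_se`,
#'   `abs_slope`, `rank`, `t0`, `anchor`.
#' @export
volatility_report <- function(fits, anchors = NULL) {
  nm <- names(fits)
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  se <- vapply(fits, `[[`, numeric(1), "slope_se")
  t0 <- vapply(seq_along(fits), function(i) {
    if (fits[[i]]$slope == 0) return(NA_real_)
    -fits[[i]]$intercept / fits[[i]]$slope
  }, numeric(1))
  out <- data.frame(location = nm, slope = unname(slope),
                    slope_se = unname(se), abs_slope = abs(unname(slope)),
                    t0 = t0,
                    anchor = if (is.null(anchors)) NA_real_
                    else unname(anchors[nm]))
  out <- out[order(-out$abs_slope, out$location), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.kelp_run_report <- function(x, ...) {
  cat("Synthetic kelp-volatility run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  %d population(s), %d metric fit(s) each\n",
              length(x$populations), length(x$config$metrics)))
  if (!is.null(x$volatility)) {
    cat("  volatility ordering (|slope|, % cover per degC):\n")
    v <- x$volatility
    for (i in seq_len(nrow(v)))
      cat(sprintf("    %d. %-14s slope %7.2f +/- %.2f  t0 %.2f (anchor %.2f)\n",
                  v$rank[i], v$location[i], v$slope[i], v$slope_se[i],
                  v$t0[i], v$anchor[i]))
  }
  for (nm in names(x$tpc))
    cat(sprintf("  TPC %-10s Topt %.2f degC, CTmax %.2f degC\n",
                nm, x$tpc[[nm]]$topt_hat, x$tpc[[nm]]$ctmax_hat))
  invisible(x)
}
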