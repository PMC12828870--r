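#' Fit a location's cover-change response slope to one metric
#'
#' Gaussian linear mixed model `delta_cover ~ metric` with a random
#' intercept per site, fitted by REML. When only one grouping level is
#' present (a location-averaged series) or the mixed fit is singular, the
#' model degrades to ordinary least squares, flagged in the result. The
#' 95% interval is Wald (`slope +/- 1.96 se`) for mixed fits and uses the
#' t quantile for the OLS path, where residual degrees of freedom are
#' known and small samples are common.
#'
#' @param table Analysis table (one row per cover-change pair) with
#'   columns `delta_cover`, the metric, the grouping factor, and
#'   optionally `clipped`.
#' @param metric_name Name of the metric column, e.g. `"mean_sst"`.
#' @param random_effect Grouping column for random intercepts (default
#'   `"site"`); `NULL` forces plain OLS.
#' @param exclude_clipped Drop rows flagged `clipped` before fitting
#'   (default TRUE): changes arriving at a cover boundary are distorted
#'   by the `[0, 100]` clip and bias the slope.
#' @return An object of class `kelp_slope_fit`: a list with `location`,
#'   `metric_name`, `slope`, `slope_se`, `ci95`, `p_value`, `intercept`,
#'   `n_obs`, `n_sites`, `site_var`, `resid_var`, `residuals`,
#'   `resid_table` (site, season_year, residual), `method`
#'   (`"lmm"`, `"ols"`, or `"ols_fallback"`), `singular`, and
#'   `convergence_warnings` (any optimiser check messages from the mixed
#'   fit).
#' @export
fit_location_slope <- function(table, metric_name, random_effect = "site",
                               exclude_clipped = TRUE) {
  tab <- as.data.frame(table)
  if (!metric_name %in% names(tab))
    stop("metric column `", metric_name, "` not found")
  if (exclude_clipped && "clipped" %in% names(tab))
    tab <- tab[!tab$clipped, , drop = FALSE]
  tab <- tab[is.finite(tab$delta_cover) & is.finite(tab[[metric_name]]), ,
             drop = FALSE]
  if (nrow(tab) < 3)
    stop("need at least 3 observations to fit a slope (have ", nrow(tab), ")")
  if (length(unique(tab[[metric_name]])) < 2)
    stop("need at least 2 distinct metric values")
  n_groups <- if (!is.null(random_effect) && random_effect %in% names(tab))
    length(unique(tab[[random_effect]])) else 1L
  use_re <- !is.null(random_effect) && n_groups >= 2L

  method <- "ols"; singular <- FALSE; model <- NULL
  conv_warnings <- character(0)
  if (use_re) {
    fml <- stats::as.formula(
      paste0("delta_cover ~ ", metric_name, " + (1 | ", random_effect, ")"))
    # keep lme4's convergence-check chatter on the fit object, not the console
    model <- tryCatch(
      withCallingHandlers(
        suppressMessages(lme4::lmer(fml, data = tab, REML = TRUE)),
        warning = function(w) {
          conv_warnings <<- c(conv_warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(model) && lme4::isSingular(model, tol = 1e-5)) {
      singular <- TRUE
      model <- NULL
    }
    method <- if (is.null(model)) "ols_fallback" else "lmm"
  }

  if (method == "lmm") {
    fe <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    slope <- unname(fe[metric_name]); slope_se <- unname(se[metric_name])
    intercept <- unname(fe["(Intercept)"])
    vc <- as.data.frame(lme4::VarCorr(model))
    site_var <- vc$vcov[vc$grp == random_effect][1]
    resid_var <- vc$vcov[vc$grp == "Residual"][1]
    ci <- slope + c(-1, 1) * 1.96 * slope_se
    p <- 2 * stats::pnorm(-abs(slope / slope_se))
    resid <- stats::residuals(model)
  } else {
    fml <- stats::as.formula(paste0("delta_cover ~ ", metric_name))
    model <- stats::lm(fml, data = tab)
    cf <- summary(model)$coefficients
    slope <- cf[metric_name, "Estimate"]
    slope_se <- cf[metric_name, "Std. Error"]
    intercept <- cf["(Intercept)", "Estimate"]
    df <- model$df.residual
    ci <- slope + c(-1, 1) * stats::qt(0.975, df) * slope_se
    p <- cf[metric_name, "Pr(>|t|)"]
    site_var <- 0
    resid_var <- summary(model)$sigma^2
    resid <- stats::residuals(model)
  }

  resid_table <- data.frame(
    site = if (!is.null(random_effect) && random_effect %in% names(tab))
      tab[[random_effect]] else "all",
    season_year = if ("season_year" %in% names(tab))
      tab$season_year else NA_integer_,
    residual = as.numeric(resid))

  structure(list(
    location = if ("location" %in% names(tab))
      paste(unique(tab$location), collapse = "+") else NA_character_,
    metric_name = metric_name,
    slope = slope, slope_se = slope_se, ci95 = ci, p_value = p,
    intercept = intercept, n_obs = nrow(tab), n_sites = n_groups,
    site_var = site_var, resid_var = resid_var,
    residuals = as.numeric(resid), resid_table = resid_table,
    method = method, singular = singular,
    convergence_warnings = conv_warnings),
    class = "kelp_slope_fit")
}

#' @export
print.kelp_slope_fit <- function(x, ...) {
  cat(sprintf("Cover-change response fit (%s): %s\n", x$method, x$location))
  cat(sprintf("  %s slope: %.3f +/- %.3f  [%.3f, %.3f]  p = %.3g\n",
              x$metric_name, x$slope, x$slope_se, x$ci95[1], x$ci95[2],
              x$p_value))
  cat(sprintf("  n = %d obs, %d site(s); site var %.3f, resid var %.3f\n",
              x$n_obs, x$n_sites, x$site_var, x$resid_var))
  invisible(x)
}

#' Temperature at which predicted cover change crosses zero
#'
#' For a fit against an absolute-temperature metric, the modelled zero
#' change occurs at `t0 = -intercept / slope`; `diff` compares it with a
#' supplied climatological anchor.
#'
#' @param fit A [fit_location_slope()] result.
#' @param clim_anchor Climatological warm-season mean SST (deg C).
#' @return List with `t0`, `clim_anchor`, `diff = t0 - clim_anchor`.
#' @export
zero_crossing_threshold <- function(fit, clim_anchor) {
  stopifnot(inherits(fit, "kelp_slope_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0)
    stop("zero-crossing threshold undefined: slope is zero")
  t0 <- -fit$intercept / fit$slope
  list(t0 = t0, clim_anchor = clim_anchor, diff = t0 - clim_anchor)
}

#' Lag-1 autocorrelation of residuals within sites
#'
#' Per site, the Pearson correlation between residuals in consecutive
#' seasons (only season pairs one year apart are used). Sites with fewer
#' than 3 residuals, fewer than 2 usable pairs, or zero residual variance
#' are excluded.
#'
#' @param fit A [fit_location_slope()] result (carries per-observation
#'   residuals indexed by site and season).
#' @return List with `per_site` (named numeric vector of r), `mean_r`,
#'   and `n_sites_used`. Empty (with a warning) when no site qualifies.
#' @export
residual_lag1_autocorr <- function(fit) {
  stopifnot(inherits(fit, "kelp_slope_fit"))
  rt <- fit$resid_table
  per_site <- c()
  for (grp in split(rt, rt$site)) {
    grp <- grp[order(grp$season_year), , drop = FALSE]
    if (nrow(grp) < 3) next
    lag1 <- which(diff(grp$season_year) == 1)
    if (length(lag1) < 2) next
    x <- grp$residual[lag1]; y <- grp$residual[lag1 + 1]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    per_site[as.character(grp$site[1])] <- stats::cor(x, y)
  }
  if (length(per_site) == 0) {
    warning("no site has enough consecutive residuals for lag-1 autocorrelation")
    return(list(per_site = numeric(0), mean_r = NA_real_, n_sites_used = 0L))
  }
  list(per_site = per_site, mean_r = mean(per_site),
       n_sites_used = length(per_site))
}

#' Slope distribution under random downsampling
#'
#' Repeatedly draws `n_target` observation rows without replacement,
#' refits the slope, and summarises the resampled estimates — a
#' robustness check that a steep slope is not an artefact of dataset
#' size.
#'
#' @param table Analysis table (see [fit_location_slope()]).
#' @param metric_name Metric column to fit against.
#' @param n_target Rows per draw; must allow a fit (>= 3) and not exceed
#'   the available rows.
#' @param reps Number of draws (default 1000).
#' @param seed Integer seed.
#' @param ... Passed to [fit_location_slope()].
#' @return List with `n_target`, `reps`, `slopes` (length `reps`, NA
#'   where a draw was unfittable), `summary` (mean, sd, 2.5% and 97.5%
#'   quantiles over non-NA slopes), `seed`, `n_failed`.
#' @export
downsample_slope_distribution <- function(table, metric_name, n_target,
                                          reps = 1000, seed = 1L, ...) {
  tab <- as.data.frame(table)
  if ("clipped" %in% names(tab)) tab <- tab[!tab$clipped, , drop = FALSE]
  n <- nrow(tab)
  if (n_target < 3) stop("`n_target` below the minimum fittable size (3)")
  if (n_target > n) stop("`n_target` exceeds the ", n, " available rows")
  slopes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n_target)
      tryCatch(fit_location_slope(tab[idx, , drop = FALSE], metric_name,
                                  exclude_clipped = FALSE, ...)$slope,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- slopes[!is.na(slopes)]
  list(n_target = as.integer(n_target), reps = as.integer(reps),
       slopes = slopes,
       summary = c(mean = mean(ok), sd = stats::sd(ok),
                   q2.5 = unname(stats::quantile(ok, 0.025)),
                   q97.5 = unname(stats::quantile(ok, 0.975))),
       seed = as.integer(seed), n_failed = sum(is.na(slopes)))
}

#' Refit after excluding one season
#'
#' Drops every observation from the given season and refits — the
#' robustness check that a response is not driven by a single extreme
#' summer.
#'
#' @param table Analysis table.
#' @param metric_name Metric column to fit against.
#' @param season_year Season to exclude.
#' @param ... Passed to [fit_location_slope()].
#' @return A [fit_location_slope()] result on the reduced table.
#' @export
sensitivity_exclude_season <- function(table, metric_name, season_year, ...) {
  tab <- as.data.frame(table)
  fit_location_slope(tab[tab$season_year != season_year, , drop = FALSE],
                     metric_name, ...)
}
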