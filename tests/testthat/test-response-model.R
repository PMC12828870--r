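# analysis-table fixture: exact linear response across sites
exact_table <- function(slope = -5, intercept_t = 20, sites = 3,
                        seasons = 2001:2010, t = NULL) {
  if (is.null(t)) t <- 18 + (seq_along(seasons) %% 5)
  do.call(rbind, lapply(seq_len(sites), function(s) {
    data.frame(location = "loc", site = paste0("s", s),
               season_year = seasons,
               mean_sst = t, delta_cover = slope * (t - intercept_t))
  }))
}

test_that("noiseless linear data recover the slope exactly", {
  fit <- fit_location_slope(exact_table(slope = -5), "mean_sst")
  expect_equal(fit$slope, -5, tolerance = 1e-8)
  expect_lt(fit$resid_var, 1e-10)
  expect_equal(fit$n_sites, 3)
})

test_that("single-site fits equal the closed-form OLS oracle", {
  tab <- exact_table(sites = 1)
  withr::with_seed(2, tab$delta_cover <- tab$delta_cover + rnorm(nrow(tab)))
  fit <- fit_location_slope(tab, "mean_sst")
  expect_equal(fit$method, "ols")
  x <- tab$mean_sst; y <- tab$delta_cover
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, beta_hat, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - beta_hat * mean(x), tolerance = 1e-12)
})

test_that("mixed and OLS slopes agree when there is no site variance", {
  pop <- toy_population(true_slope = -6, anchor = 20, t_summer = 20,
                        n_sites = 4, site_sd = 0, resid_sd = 3,
                        years = c(2000, 2015), seed = 9)
  pop$sst$noise_sd <- 0.4; pop$sst$ar1_coeff <- 0.8
  tab <- population_analysis_table(pop)
  f_mm <- fit_location_slope(tab, "mean_sst")
  f_ols <- fit_location_slope(tab, "mean_sst", random_effect = NULL)
  expect_equal(f_mm$slope, f_ols$slope, tolerance = 1e-6)
})

test_that("slope is equivariant under shifting and scaling the metric", {
  pop <- default_populations(5)$jervis_bay
  tab <- population_analysis_table(pop)
  f <- fit_location_slope(tab, "mean_sst")
  shifted <- tab; shifted$mean_sst <- shifted$mean_sst + 3
  f_shift <- fit_location_slope(shifted, "mean_sst")
  expect_equal(f_shift$slope, f$slope, tolerance = 1e-6)
  expect_equal(f_shift$intercept, f$intercept - 3 * f$slope, tolerance = 1e-4)
  scaled <- tab; scaled$mean_sst <- scaled$mean_sst * 2
  f_scale <- fit_location_slope(scaled, "mean_sst")
  expect_equal(f_scale$slope, f$slope / 2, tolerance = 1e-6)
})

test_that("fits recover the generating slope on default synthetic data", {
  pop <- default_populations(7)$jurien
  tab <- population_analysis_table(pop)
  fit <- fit_location_slope(tab, "mean_sst")
  expect_true(fit$ci95[1] <= -10 && -10 <= fit$ci95[2])
  expect_equal(fit$slope, -10, tolerance = 0.25)
})

test_that("fit preconditions are enforced", {
  tab <- exact_table(sites = 1)
  expect_error(fit_location_slope(tab[1:2, ], "mean_sst"), "at least 3")
  tab$mean_sst <- 20
  expect_error(fit_location_slope(tab, "mean_sst"), "distinct")
  expect_error(fit_location_slope(tab, "nope"), "not found")
})

test_that("zero-crossing threshold is -intercept/slope", {
  fit <- structure(list(slope = -2, intercept = 40), class = "kelp_slope_fit")
  th <- zero_crossing_threshold(fit, clim_anchor = 19)
  expect_equal(th$t0, 20)
  expect_equal(th$diff, 1)
  fit0 <- structure(list(slope = 0, intercept = 40), class = "kelp_slope_fit")
  expect_error(zero_crossing_threshold(fit0, 19), "slope is zero")
})

test_that("threshold of anchored synthetic data sits at the anchor", {
  pop <- toy_population(true_slope = -10, anchor = 20, t_summer = 20,
                        n_sites = 2, years = c(2000, 2010), seed = 3)
  pop$sst$noise_sd <- 0.3; pop$sst$ar1_coeff <- 0.8
  tab <- population_analysis_table(pop)
  fit <- fit_location_slope(tab, "mean_sst")
  th <- zero_crossing_threshold(fit, 20)
  expect_equal(th$t0, 20, tolerance = 1e-6)
})

test_that("alternating residuals give lag-1 autocorrelation of -1", {
  # x constant within season pairs keeps the fitted line flat, so the
  # residuals are the alternating series itself
  m <- 5
  tab <- data.frame(location = "loc", site = "s1", season_year = 1:(2 * m),
                    mean_sst = rep(1:m, each = 2),
                    delta_cover = rep(c(-1, 1), m))
  fit <- fit_location_slope(tab, "mean_sst")
  expect_equal(unname(fit$residuals), rep(c(-1, 1), m), tolerance = 1e-10)
  ac <- residual_lag1_autocorr(fit)
  expect_equal(unname(ac$per_site["s1"]), -1, tolerance = 1e-10)
})

test_that("zero-variance sites are excluded and means average across sites", {
  rt <- data.frame(site = rep(c("a", "b", "c"), each = 6),
                   season_year = rep(1:6, 3),
                   residual = c(rep(0, 6),                 # excluded: no variance
                                c(1, -1, 1, -1, 1, -1),    # r = -1
                                c(1, -1, 1, -1, 1, -1)))
  fit <- structure(list(resid_table = rt), class = "kelp_slope_fit")
  ac <- residual_lag1_autocorr(fit)
  expect_equal(ac$n_sites_used, 2)
  expect_equal(ac$mean_r, -1)
  none <- structure(list(resid_table = rt[rt$site == "a", ]),
                    class = "kelp_slope_fit")
  expect_warning(ac0 <- residual_lag1_autocorr(none), "no site")
  expect_true(is.na(ac0$mean_r))
})

test_that("downsampling at full size reproduces the full-data slope", {
  pop <- default_populations(2)$jervis_bay
  tab <- population_analysis_table(pop)
  tab <- tab[!tab$clipped, ]
  full <- fit_location_slope(tab, "mean_sst")
  ds <- downsample_slope_distribution(tab, "mean_sst", n_target = nrow(tab),
                                      reps = 5, seed = 1)
  expect_true(all(abs(ds$slopes - full$slope) < 1e-8))
})

test_that("downsampled slopes centre on the full-data slope", {
  pop <- default_populations(2)$jervis_bay
  tab <- population_analysis_table(pop)
  full <- fit_location_slope(tab, "mean_sst")
  ds <- downsample_slope_distribution(tab, "mean_sst", n_target = 60,
                                      reps = 60, seed = 4)
  expect_equal(ds$summary[["mean"]], full$slope,
               tolerance = 0.5 * full$slope_se / abs(full$slope))
  expect_identical(ds$slopes,
                   downsample_slope_distribution(tab, "mean_sst",
                                                 n_target = 60, reps = 60,
                                                 seed = 4)$slopes)
  expect_error(downsample_slope_distribution(tab, "mean_sst", n_target = 2),
               "minimum")
})

test_that("excluding a season refits on the remaining data", {
  tab <- exact_table(slope = -5)
  full <- fit_location_slope(tab, "mean_sst")
  same <- sensitivity_exclude_season(tab, "mean_sst", 1990)  # absent season
  expect_equal(same$slope, full$slope)
  expect_equal(same$n_obs, full$n_obs)
  drop1 <- sensitivity_exclude_season(tab, "mean_sst", 2001)
  expect_equal(drop1$n_obs, full$n_obs - 3)
  expect_error(
    fit_location_slope(tab[tab$season_year > 2009, ][0, ], "mean_sst"))
})

test_that("slope sign survives removing the extreme season", {
  pop <- default_populations(4)$jurien
  tab <- population_analysis_table(pop)
  extreme <- tab$season_year[which.max(tab$mean_sst)]
  fit <- sensitivity_exclude_season(tab, "mean_sst", extreme)
  expect_lt(fit$slope, 0)
})
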