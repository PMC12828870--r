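test_that("climatology of a constant series is that constant", {
  clim <- compute_climatology(constant_sst(15, c(2000, 2002)), c(2000, 2002))
  expect_equal(clim$mean_by_doy, rep(15, 365))
  expect_equal(clim$p90_by_doy, rep(15, 365))
})

test_that("two-year climatology is the direct two-term average", {
  y1 <- generate_sst(sst_config(mean_sst = 14, seasonal_amplitude = 2,
                                years = c(2001, 2001)))
  y2 <- y1
  y2$date <- y1$date + 365
  y2$sst_c <- y1$sst_c + 2
  series <- rbind(y1, y2)
  clim <- compute_climatology(series, c(2001, 2002), window_days = 1)
  # oracle: average of the two years, computed directly per day-of-year
  expect_equal(clim$mean_by_doy, y1$sst_c + 1)
})

test_that("unsmoothed climatology of a pure sinusoid is the sinusoid", {
  sst <- generate_sst(sst_config(mean_sst = 15, seasonal_amplitude = 3,
                                 years = c(2001, 2001)))
  clim <- compute_climatology(sst, c(2001, 2001), window_days = 1)
  expect_equal(clim$mean_by_doy, sst$sst_c)
  expect_equal(climatology_at(clim, sst$date), sst$sst_c)
})

test_that("Feb 29 shares the Feb 28 climatology slot", {
  sst <- constant_sst(10, c(2004, 2004))   # leap year
  sst$sst_c[sst$date == as.Date("2004-02-29")] <- 12
  clim <- compute_climatology(sst, c(2004, 2004), window_days = 1)
  expect_equal(clim$mean_by_doy[59], 11)   # pooled Feb 28 + Feb 29
  expect_equal(climatology_at(clim, as.Date("2004-02-29")),
               climatology_at(clim, as.Date("2004-02-28")))
})

test_that("warm-season slice has 151 or 152 days and errors when absent", {
  sst <- constant_sst(15, c(2000, 2002))
  expect_equal(nrow(warm_season_slice(sst, 2001)), 151)  # Feb 2001 non-leap
  sst2 <- constant_sst(15, c(2003, 2004))
  expect_equal(nrow(warm_season_slice(sst2, 2004)), 152) # Feb 2004 leap
  jan_start <- sst[sst$date >= as.Date("2001-01-01"), ]
  expect_error(warm_season_slice(jan_start, 2001), "warm season 2001")
})

test_that("null and rectangular anomalies give closed-form metrics", {
  sst <- constant_sst(15, c(2000, 2002))
  clim <- compute_climatology(sst, c(2000, 2002))
  m0 <- warm_season_metrics(sst, clim, 2001)
  expect_equal(m0$max_intensity, 0)
  expect_equal(m0$cum_intensity, 0)
  expect_equal(m0$tendency, 0)
  expect_equal(m0$mean_sst, 15)
  # +1 degC across the whole 151-day season: rectangle area
  warm <- sst
  season <- warm$date >= as.Date("2000-12-01") & warm$date <= as.Date("2001-04-30")
  warm$sst_c[season] <- warm$sst_c[season] + 1
  m1 <- warm_season_metrics(warm, clim, 2001)
  expect_equal(m1$n_days, 151)
  expect_equal(m1$max_intensity, 1)
  expect_equal(m1$cum_intensity, 151)
  expect_equal(m1$mean_sst, 16)
  expect_equal(m1$max_monthly_sst, 16)
})

test_that("triangular anomaly reproduces the hand-summed oracle", {
  sst <- constant_sst(15, c(2000, 2002))
  clim <- compute_climatology(sst, c(2000, 2002))
  tri <- sst
  # rise 0 -> 3 over 30 days then fall 3 -> 0 over 30 days, from 1 Jan 2001
  up <- seq(0, 3, length.out = 31)[-1]
  down <- seq(3, 0, length.out = 31)[-1]
  idx <- match(seq(as.Date("2001-01-01"), by = "day", length.out = 60),
               tri$date)
  tri$sst_c[idx] <- tri$sst_c[idx] + c(up, down)
  m <- warm_season_metrics(tri, clim, 2001, tendency_window_days = 30)
  expect_equal(m$max_intensity, 3)
  expect_equal(m$cum_intensity, sum(c(up, down)))   # discrete triangle area
  expect_equal(m$tendency, 0.1)                      # 3 degC over 30 days
})

test_that("metrics are invariant to input row order", {
  sst <- generate_sst(sst_config(mean_sst = 15, seasonal_amplitude = 3,
                                 ar1_coeff = 0.6, noise_sd = 0.4,
                                 years = c(2000, 2002), seed = 3))
  clim <- compute_climatology(sst, c(2000, 2002))
  shuffled <- sst[sample(nrow(sst)), ]
  expect_equal(warm_season_metrics(shuffled, clim, 2001),
               warm_season_metrics(sst, clim, 2001))
})

test_that("adding a constant shifts mean and max intensity exactly", {
  sst <- generate_sst(sst_config(mean_sst = 15, seasonal_amplitude = 3,
                                 ar1_coeff = 0.6, noise_sd = 0.4,
                                 years = c(2000, 2002), seed = 5))
  clim <- compute_climatology(sst, c(2000, 2002))
  m <- warm_season_metrics(sst, clim, 2001)
  up <- sst; up$sst_c <- up$sst_c + 0.7
  m_up <- warm_season_metrics(up, clim, 2001)
  expect_equal(m_up$mean_sst, m$mean_sst + 0.7)
  expect_equal(m_up$max_intensity, m$max_intensity + 0.7)
  expect_gte(m_up$cum_intensity, m$cum_intensity)
})

test_that("simple event-detection cases behave as defined", {
  sst <- constant_sst(15, c(2000, 2001))
  clim <- compute_climatology(sst, c(2000, 2001))
  # constant series never exceeds its own 90th percentile
  expect_equal(nrow(detect_mhw_events(sst, clim)), 0)
  # one 10-day excursion
  one <- sst
  idx <- match(seq(as.Date("2001-03-01"), by = "day", length.out = 10),
               one$date)
  one$sst_c[idx] <- 17
  ev <- detect_mhw_events(one, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 10)
  expect_equal(ev$start_date, as.Date("2001-03-01"))
  expect_equal(ev$peak_anomaly, 2)
  # two 5-day excursions bridged by a 2-day dip merge into one 12-day event
  two <- sst
  d <- as.Date("2001-03-01") + 0:11
  hot <- setdiff(seq_along(d), 6:7)
  two$sst_c[match(d[hot], two$date)] <- 17
  ev2 <- detect_mhw_events(two, clim)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration, 12)
})

test_that("event detection matches a brute-force day-by-day oracle", {
  sst <- constant_sst(15, c(2000, 2001))
  clim <- compute_climatology(sst, c(2000, 2001))
  thr <- climatology_at(clim, sst$date, "p90")
  withr::with_seed(99, {
    for (rep in 1:200) {
      s <- sst
      n <- nrow(s)
      # random warm excursions on top of the constant base
      for (k in seq_len(sample(1:4, 1))) {
        i0 <- sample(n - 15, 1)
        len <- sample(1:12, 1)
        s$sst_c[i0:(i0 + len - 1)] <- s$sst_c[i0:(i0 + len - 1)] +
          runif(len, 0.5, 3)
      }
      got <- detect_mhw_events(s, clim)
      want <- brute_force_events(s$sst_c, thr, s$date)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start_date, s$date[want$start])
        expect_equal(got$end_date, s$date[want$end])
      }
    }
  })
})
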