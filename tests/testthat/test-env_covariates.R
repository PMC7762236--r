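test_that("day length model honours its symmetries and the scan oracle", {
  # equator with no twilight: exactly 12 h on any day
  expect_equal(day_length(0, c(1, 80, 172, 300), 0), rep(12, 4),
               tolerance = 1e-12)
  # hemispheric complement: D(L) + D(-L) = 24 at p = 0
  expect_equal(day_length(41.63, 172, 0) + day_length(-41.63, 172, 0), 24,
               tolerance = 1e-9)
  # against the minute-scan solar-altitude oracle at the three site latitudes
  for (L in c(41.63, 27.35, 19.52))
    for (J in c(15, 80, 172, 260, 355))
      expect_equal(day_length(L, J, 6), ora_day_length_scan(L, J, 6),
                   tolerance = 0.1)
  # monotone in the twilight coefficient ...
  p_grid <- seq(0, 12, by = 2)
  dl <- day_length(41.63, 100, p_grid)
  expect_true(all(diff(dl) > 0))
  # ... and in day of year up to the June solstice for northern latitudes
  dl2 <- day_length(41.63, 1:172, 6)
  expect_true(all(diff(dl2) > 0))
  expect_error(day_length(40, 0), "day_of_year")
  expect_warning(day_length(80, 172, 6), "saturated")
})

test_that("photo-thermal units follow the degree-hour definition", {
  mkwx <- function(tmean) {
    n <- length(tmean)
    data.frame(site = "S", year = 2001L,
               date = seq(as.Date("2001-03-01"), by = "day",
                          length.out = n),
               tmin_c = tmean - 2, tmax_c = tmean + 2, tmean_c = tmean,
               rad_mj_m2 = 15)
  }
  # all days at the base temperature: zero forcing
  wx <- mkwx(rep(5, 10))
  expect_equal(photothermal_units(wx, wx$date[1], wx$date[10], 30,
                                  t_base = 5), 0)
  # constant 20 C at the equator with p = 0 (12 h): 10 * 20 * 12
  wx <- mkwx(rep(20, 10))
  expect_equal(photothermal_units(wx, wx$date[1], wx$date[10], 0, 0, 0),
               2400, tolerance = 1e-9)
  # mixed window against a per-day loop oracle
  wx <- mkwx(c(-2, 5, 10, 0, 8))
  lat <- 27.35
  oracle <- 0
  for (i in 1:5)
    oracle <- oracle + max(wx$tmean_c[i], 0) *
      day_length(lat, as.integer(format(wx$date[i], "%j")), 6)
  expect_equal(photothermal_units(wx, wx$date[1], wx$date[5], lat), oracle)
  # a gap in the series is a hard error naming the missing date
  expect_error(photothermal_units(wx[-3, ], wx$date[1], wx$date[5], lat),
               "2001-03-03")
})

test_that("window aggregates match an independent slicing oracle", {
  sim <- simulate_trial(sim_config(seed = 31))
  pl <- derive_traits(sim$plots)
  cv <- window_aggregates(pl, sim$weather, sim$experiments)

  # one fully-staged Spain plot re-aggregated by hand
  i <- which(pl$site == "Spain" & pl$year == 2011 & pl$block == 1)[1]
  wx <- sim$weather[sim$weather$site == "Spain" & sim$weather$year == 2011, ]
  lat <- 41.63
  win <- function(d0, d1) wx[wx$date >= d0 & wx$date <= d1, ]
  ef <- win(pl$date_emergence[i], pl$date_flowering[i])
  fm <- win(pl$date_flowering[i], pl$date_maturity[i])
  expect_equal(cv$tmean_ef[i], mean(ef$tmean_c))
  expect_equal(cv$tmean_fm[i], mean(fm$tmean_c))
  expect_equal(cv$rmean_ef[i], mean(ef$rad_mj_m2))
  expect_equal(cv$rac_ef[i], sum(ef$rad_mj_m2))
  expect_equal(cv$rmean_fm[i], mean(fm$rad_mj_m2))
  f11 <- win(pl$date_flowering[i] - 5, pl$date_flowering[i] + 5)
  expect_equal(nrow(f11), 11L)
  expect_equal(cv$tmax_f[i], mean(f11$tmax_c))
  expect_equal(cv$dlmean_ef[i],
               mean(day_length(lat, as.integer(format(ef$date, "%j")), 6)))
  drf <- win(pl$date_double_ridge[i], pl$date_flowering[i])
  expect_equal(cv$rmean_drf[i], mean(drf$rad_mj_m2))
  tsf <- win(pl$date_terminal_spikelet[i], pl$date_flowering[i])
  ptu_oracle <- sum(pmax(tsf$tmean_c, 0) *
                      day_length(lat, as.integer(format(tsf$date, "%j")), 6))
  expect_equal(cv$ptu_tsf[i], ptu_oracle)

  # accumulated = mean x closed-interval day count, exactly, for all plots
  len_ef <- as.integer(pl$date_flowering - pl$date_emergence) + 1L
  expect_equal(cv$rac_ef, cv$rmean_ef * len_ef, tolerance = 1e-12)

  # covariates needing absent stage dates are absent, not imputed
  no_stage <- pl$year %in% c(2007, 2008)
  expect_true(all(is.na(cv$rmean_drf[no_stage])))
  expect_true(all(is.na(cv$ptu_tsf[no_stage])))
  expect_true(all(!is.na(cv$tmean_ef)))

  # PTU is nonnegative everywhere it exists
  expect_true(all(cv$ptu_tsf >= 0, na.rm = TRUE))

  # weather not covering a window is a hard error with the date range
  wx_cut <- sim$weather[sim$weather$date <= max(pl$date_flowering), ]
  expect_error(window_aggregates(pl, wx_cut, sim$experiments),
               "flowering-maturity")
})

test_that("trivial window symmetries hold", {
  # constant temperature: the window mean is that constant; a linear tmax
  # ramp centred on flowering averages to the flowering-day value
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = 200)
  wx <- data.frame(site = "S", year = 2001L, date = dates,
                   tmin_c = 10, tmax_c = 20 + seq_along(dates) * 0.3,
                   tmean_c = 15, rad_mj_m2 = 12)
  g <- tiny_genotypes(1)
  pl <- data.frame(site = "S", year = 2001L, block = 1L, genotype = "g01",
                   date_emergence = dates[10],
                   date_double_ridge = as.Date(NA),
                   date_terminal_spikelet = as.Date(NA),
                   date_heading = as.Date(NA),
                   date_flowering = dates[100], date_maturity = dates[150],
                   gy_g_m2 = 600, gw_mg = 40)
  ex <- data.frame(site = "S", year = 2001L, latitude_deg = 41.63,
                   sowing_date = dates[1])
  cv <- window_aggregates(pl, wx, ex)
  expect_equal(cv$tmean_ef, 15)
  expect_equal(cv$tmax_f, wx$tmax_c[100])   # symmetric window, linear ramp
})
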