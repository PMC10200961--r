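make_hh_day <- function(date = as.Date("2001-06-01"), n_day = 24,
                        gpp = 10, le = 200, h = 100, sw = 400) {
  hh <- seq(0, 23.5, by = 0.5)
  day <- rep(FALSE, 48)
  day[seq(13, 12 + n_day)] <- TRUE
  data.frame(date = date, doy = as.integer(format(date, "%j")),
             hour = hh + 0.25,
             sw_in = ifelse(day, sw, 0), ta = 18, rh = 0.7, vpd = 0.62,
             ws = 2.5, ca = 410, le = ifelse(day, le, 0),
             h = ifelse(day, h, 0), g = 0,
             gpp = ifelse(day, gpp, 0), qc = 0L)
}

test_that("daytime screening applies the strict 5 W/m2 threshold and flags", {
  rec <- data.frame(sw_in = c(5.0, 5.1, 4.9, 300, NA), qc = c(0, 0, 0, 2, 0))
  kept <- qc_filter_daytime(rec)
  expect_equal(kept$sw_in, 5.1)  # 5.0 dropped (strict), 300 fails QC
  # an all-night day retains nothing
  night <- data.frame(sw_in = rep(0, 48))
  expect_equal(nrow(qc_filter_daytime(night)), 0)
  # without a qc column only the radiation screen applies
  expect_equal(nrow(qc_filter_daytime(data.frame(sw_in = c(3, 30, 300)))), 2)
})

test_that("daily aggregation converts units correctly", {
  rec <- qc_filter_daytime(make_hh_day(n_day = 24, gpp = 10))
  d <- aggregate_daily(rec)
  # 10 umol/m2/s over 12 h: 10 * 12.011e-6 * 43200 = 5.18875 gC
  expect_equal(d$gpp_obs, 10 * 12.011e-6 * 43200, tolerance = 1e-12)
  expect_equal(d$gpp_obs, 5.189, tolerance = 1e-4)
  expect_equal(d$daytime_s, 43200)
  # LE to water depth through lambda(T): LE W/m2 * s / (lambda MJ/kg * 1e6)
  lam <- psychrometrics(18)$lambda
  expect_equal(d$et_obs, 200 * 43200 / (lam * 1e6), tolerance = 1e-12)
  # single retained record: daily mean equals that record
  one <- make_hh_day()[25, ]
  expect_equal(aggregate_daily(one)$ta, one$ta)
})

test_that("aggregation conserves carbon mass across days", {
  rec <- rbind(make_hh_day(as.Date("2001-06-01"), gpp = 8),
               make_hh_day(as.Date("2001-06-02"), gpp = 12))
  rec <- qc_filter_daytime(rec)
  d <- aggregate_daily(rec)
  expect_equal(sum(d$gpp_obs), sum(rec$gpp) * 12.011e-6 * 1800,
               tolerance = 1e-12)
})

test_that("uWUE partitioning recovers a degenerate proportional series", {
  set.seed(5)
  n <- 80
  et <- runif(n, 0.5, 4)
  vpd <- runif(n, 0.3, 2)
  cc <- 7.3
  daily <- data.frame(et_obs = et, vpd = vpd,
                      gpp_obs = cc * et / sqrt(vpd))
  out <- partition_transpiration_uwue(daily)
  # GPP sqrt(VPD) = c * ET exactly: the quantile slope is c and Tc = ET
  expect_equal(attr(out, "uwue_p"), cc, tolerance = 1e-12)
  expect_equal(out$tc_obs, et, tolerance = 1e-12)
  # noisy ratios above 1 clamp to Tc = ET
  daily2 <- daily
  daily2$gpp_obs[1] <- daily2$gpp_obs[1] * 3
  out2 <- partition_transpiration_uwue(daily2)
  expect_true(all(out2$tc_obs <= out2$et_obs + 1e-12))
  expect_equal(out2$tc_obs[1], out2$et_obs[1])
  # too few days is an error
  expect_error(partition_transpiration_uwue(daily[1:10, ]), "valid days")
  # non-positive ET days are flagged, not partitioned
  daily3 <- daily
  daily3$et_obs[2] <- 0
  expect_true(is.na(partition_transpiration_uwue(daily3)$tc_obs[2]))
})

test_that("season identification segments a sinusoidal climate", {
  doy <- rep(1:365, 3)
  ta <- 10 - 10 * cos(2 * pi * (doy - 15) / 365)
  s <- identify_seasons(data.frame(doy = doy, ta = ta))
  # contiguity: spring end + 1 = summer start, summer end + 1 = autumn start
  expect_equal(s$spring[2] + 1, s$summer[1])
  expect_equal(s$summer[2] + 1, s$autumn[1])
  # the annual maximum (doy ~ 197) falls inside summer
  expect_true(s$summer[1] <= 197 && 197 <= s$summer[2])
  # closed-form crossings of the sinusoid against the exact quartiles:
  # cos quartiles at doy 15 + 365/8 and 15 + 3*365/8
  expect_equal(s$spring[1], 15 + 365 / 8, tolerance = 4 / 60)
  expect_equal(s$summer[1], 15 + 3 * 365 / 8, tolerance = 4 / 152)
  # symmetric autumn: cooling crossings mirrored about doy 197.5
  expect_equal(s$autumn[2], 380 - 365 / 8, tolerance = 4 / 334)
  # constant temperature has no seasonal cycle
  expect_error(identify_seasons(data.frame(doy = 1:365, ta = rep(7, 365))),
               "no seasonal cycle")
  # labelling covers the windows and leaves winter NA
  lab <- season_of_doy(c(1, s$spring[1], s$summer[1], s$autumn[2], 360), s)
  expect_equal(lab, c(NA, "spring", "summer", "autumn", NA))
})

test_that("LAI interpolation is linear then Savitzky-Golay smoothed", {
  # two points: exact linear midpoint, no smoothing possible
  s2 <- data.frame(t = c(1, 9), lai = c(1, 3), fpar = c(0.3, 0.7))
  out <- interpolate_lai_fpar(s2)
  expect_equal(out$lai[out$t == 5], 2)
  # constants are preserved by the filter
  sc <- data.frame(t = seq(1, 81, 8), lai = 4, fpar = 0.8)
  outc <- interpolate_lai_fpar(sc)
  expect_equal(outc$lai, rep(4, 81), tolerance = 1e-12)
  # a quadratic daily series is reproduced exactly by an order-2 filter
  tt <- 1:41
  sq <- data.frame(t = tt, lai = 0.002 * tt^2, fpar = 0.5)
  outq <- interpolate_lai_fpar(sq)
  expect_equal(outq$lai, 0.002 * tt^2, tolerance = 1e-9)
  # physical clipping
  sn <- data.frame(t = c(1, 9, 17), lai = c(0, 0.1, 0), fpar = c(0, 0.05, 0))
  expect_true(all(interpolate_lai_fpar(sn)$lai >= 0))
  expect_error(interpolate_lai_fpar(data.frame(t = c(9, 1), lai = 1:2,
                                               fpar = c(0.1, 0.2))),
               "increasing")
  expect_error(interpolate_lai_fpar(s2[1, ]), "two composite")
})
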