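test_that("site specification validates its fields", {
  expect_error(synthetic_site(latitude = 120), "latitude")
  expect_error(synthetic_site(measurement_height = 20), "measurement_height")
  expect_error(synthetic_site(lai_curve = list(max = -1, greenup = 100,
                                               senescence = 290, slope = 10)),
               "lai_curve")
  expect_error(synthetic_site(lai_curve = list(max = 5, greenup = 300,
                                               senescence = 290, slope = 10)),
               "greenup")
  expect_error(synthetic_site(noise = list(gpp = -1, tc = 0)), "noise")
  # a single parameter set is recycled over all seasons
  spec <- synthetic_site(true_params = parameter_set(0.6, 3.9, 9, 8, "all"))
  expect_equal(spec$true_params$summer$eps_msu, 0.6)
})

test_that("generated meteorology is physical and deterministic", {
  spec <- synthetic_site(years = 1, seed = 99)
  m1 <- generate_meteo(spec)
  m2 <- generate_meteo(spec)
  expect_identical(m1, m2)  # same seed, bit-identical series
  expect_equal(nrow(m1), 365 * 48)
  # no sun below the horizon; bounded irradiance
  geo <- solar_zenith(spec$latitude, m1$doy, m1$hour)
  expect_true(all(m1$sw_in[!geo$daylight] == 0))
  expect_true(all(m1$sw_in >= 0 & m1$sw_in <= 1400))
  expect_true(all(m1$rh > 0 & m1$rh <= 1))
  expect_true(all(m1$vpd >= 0))
  # VPD is consistent with T and RH through the saturation vapour pressure
  expect_equal(m1$vpd, psychrometrics(m1$ta)$e_sat * (1 - m1$rh),
               tolerance = 1e-12)
  # saturation: RH = 1 would give VPD = 0
  sat <- which.max(m1$rh)
  if (m1$rh[sat] == 1) expect_equal(m1$vpd[sat], 0)
  # a different seed gives a different series
  expect_false(identical(m1$sw_in,
                         generate_meteo(synthetic_site(years = 1,
                                                       seed = 100))$sw_in))
})

test_that("LAI/FPAR composites follow the phenology and Beer's law", {
  spec <- synthetic_site(years = 1)
  lf <- generate_lai_fpar(spec)
  expect_equal(nrow(lf), 46)
  expect_true(all(lf$lai >= 0))
  expect_true(all(lf$fpar >= 0 & lf$fpar < 1))
  # deciduous leaf-off in midwinter, peak at the curve maximum in midsummer
  expect_lt(lf$lai[lf$doy == 1], 1e-3)
  expect_equal(max(lf$lai), spec$lai_curve$max, tolerance = 1e-3)
  # Beer-law mapping: LAI = 2, k = 0.5 -> FPAR = 1 - exp(-1)
  expect_equal(1 - exp(-tl_config()$k_beer * 2), 0.6321, tolerance = 1e-4)
  expect_equal(lf$fpar, 1 - exp(-0.5 * lf$lai), tolerance = 1e-12)
  # FPAR monotone in LAI
  ord <- order(lf$lai)
  expect_true(all(diff(lf$fpar[ord]) >= 0))
})

test_that("forward simulation reproduces the model chain exactly at zero noise", {
  fx <- sim_noise_free()
  d <- fx$daily
  expect_equal(d$gpp_obs, d$gpp_true, tolerance = 1e-12)
  expect_equal(d$tc_obs, d$tc_true, tolerance = 1e-12)
  # winter leaf-off: no photosynthesis, conductance at the soil minimum
  bare <- which(d$lai < 1e-4)
  expect_true(length(bare) > 0)
  expect_lt(max(d$gpp_true[bare]), 1e-3)
  expect_equal(d$gs_true[bare], rep(0.001, length(bare)), tolerance = 1e-2)
  # Tc never exceeds ET
  ok <- is.finite(d$et_obs)
  expect_true(all(pmax(d$tc_obs[ok], 0) <= d$et_obs[ok] + 1e-12))
  # the downstream chain recomputes the stored truth from the drivers
  for (s in c("spring", "summer", "autumn")) {
    sel <- which(d$season == s)
    p <- fx$spec$true_params[[s]]
    g <- estimate_gpp(d$apar_sunlit[sel], d$apar_shaded[sel],
                      d$f_vpd[sel], d$f_t[sel], p)
    expect_equal(g$gpp, d$gpp_true[sel], tolerance = 1e-12)
    gs <- canopy_conductance(
      gpp_daily_to_molar_rate(g$gpp_sunlit, d$daytime_s[sel]),
      gpp_daily_to_molar_rate(g$gpp_shaded, d$daytime_s[sel]),
      d$rh[sel], d$ca[sel], p)
    expect_equal(gs, d$gs_true[sel], tolerance = 1e-12)
    expect_equal(penman_monteith_tc(fx$pm[sel, ], gs), d$tc_true[sel],
                 tolerance = 1e-12)
  }
})

test_that("doubling both LUEs doubles noiseless GPP when scalars are unity", {
  fx <- sim_noise_free()
  d <- fx$daily
  sel <- which(d$season == "summer")[1:20]
  p1 <- list(eps_msu = 0.5, eps_msh = 2.0)
  p2 <- list(eps_msu = 1.0, eps_msh = 4.0)
  g1 <- estimate_gpp(d$apar_sunlit[sel], d$apar_shaded[sel], 1, 1, p1)
  g2 <- estimate_gpp(d$apar_sunlit[sel], d$apar_shaded[sel], 1, 1, p2)
  expect_equal(g2$gpp, 2 * g1$gpp, tolerance = 1e-12)
})

test_that("FLUXNET CSV round-trips with sentinel and dialect conversions", {
  fx <- sim_noise_free()
  meteo <- embed_fluxes(fx$meteo, fx$daily)
  sub <- meteo[1:(48 * 40), ]
  sub$vpd[100] <- NA  # a gap becomes the -9999 sentinel
  path <- tempfile(fileext = ".csv")
  write_fluxnet_csv(sub, path)
  raw <- read.csv(path)
  expect_true(all(c("TIMESTAMP_START", "SW_IN_F", "GPP_DT_VUT_REF",
                    "VPD_F", "RH") %in% names(raw)))
  expect_equal(raw$VPD_F[100], -9999)
  # RH stored as percent, VPD as hPa
  expect_equal(raw$RH[1], sub$rh[1] * 100, tolerance = 1e-6)
  expect_equal(raw$VPD_F[1], sub$vpd[1] * 10, tolerance = 1e-6)
  back <- read_fluxnet_csv(path)
  for (col in c("sw_in", "ta", "rh", "ws", "ca", "le", "h", "gpp")) {
    expect_rel_equal(back[[col]][back[[col]] != 0],
                     sub[[col]][back[[col]] != 0], 1e-6)
  }
  expect_true(is.na(back$vpd[100]))
  expect_equal(back$date, sub$date)
  expect_equal(back$hour, sub$hour)
  # header order is irrelevant: permute columns and reparse
  perm <- raw[, sample(names(raw))]
  path2 <- tempfile(fileext = ".csv")
  write.csv(perm, path2, row.names = FALSE)
  back2 <- read_fluxnet_csv(path2)
  expect_equal(back2$sw_in, back$sw_in)
  expect_error(write_fluxnet_csv(sub[0, ], tempfile()), "no records")
})

test_that("embedded half-hourly fluxes aggregate back to the daily values", {
  fx <- sim_noise_free()
  meteo <- embed_fluxes(fx$meteo, fx$daily)
  agg <- aggregate_daily(qc_filter_daytime(meteo))
  idx <- match(fx$daily$date, agg$date)
  expect_rel_equal(agg$gpp_obs[idx][abs(fx$daily$gpp_obs) > 1e-6],
                   fx$daily$gpp_obs[abs(fx$daily$gpp_obs) > 1e-6], 1e-9)
  ok <- fx$daily$et_obs > 1e-6
  expect_rel_equal(agg$et_obs[idx][ok], fx$daily$et_obs[ok], 1e-9)
  # available energy is preserved by the embedding
  expect_rel_equal(agg$a_mj[idx], fx$daily$a_mj, 1e-9)
})
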