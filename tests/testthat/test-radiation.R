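test_that("solar zenith follows declination geometry", {
  # equator, equinox (doy ~ 80), solar noon: sun overhead
  eq <- solar_zenith(0, 80, 12)
  expect_lt(eq$theta * 180 / pi, 1.5)
  # solstice at a mid-latitude site: zenith = latitude - declination
  noon <- solar_zenith(51.08, 172, 12)
  expect_equal(noon$theta * 180 / pi, 51.08 - 23.44, tolerance = 0.5 / 27)
  # solar midnight is not daylight
  expect_false(solar_zenith(51.08, 172, 0)$daylight)
  expect_error(solar_zenith(95, 100, 12), "latitude")
})

test_that("PAR is 0.45 of shortwave", {
  expect_equal(par_from_shortwave(0), 0)
  expect_equal(par_from_shortwave(500), 225)
  expect_equal(par_from_shortwave(1000), 450)
  expect_error(par_from_shortwave(-1), "non-negative")
})

test_that("direct/diffuse split closes and behaves in the overcast limit", {
  cfg <- tl_config()
  # overcast limit: clearness -> 0 gives a diffuse-dominated sky
  expect_gte(diffuse_fraction(0, cfg), 0.95)
  expect_equal(diffuse_fraction(0.5, cfg),
               min(1, max(0.1, sum(cfg$diffuse_coefs * 0.5^(0:4)))))
  # closure to machine precision on random skies
  set.seed(1)
  sw <- runif(200, 0, 1000)
  ct <- runif(200, 0.05, 1)
  sp <- split_direct_diffuse(0.45 * sw, sw, sample(1:365, 200, TRUE), ct, cfg)
  expect_equal(sp$par_dir + sp$par_dif, sp$par, tolerance = 1e-12)
  expect_true(all(sp$par_dir >= 0 & sp$par_dif >= 0))
  # night: everything zero
  spn <- split_direct_diffuse(100, 220, 100, -0.2, cfg)
  expect_equal(unlist(spn[c("par", "par_dir", "par_dif")]),
               c(par = 0, par_dir = 0, par_dif = 0))
})

test_that("sunlit/shaded LAI partition matches the closed form", {
  cfg <- tl_config(clumping = 0.8)
  expect_equal(unlist(partition_lai(0, 0.5, cfg)),
               c(lai_sunlit = 0, lai_shaded = 0))
  # saturation: sunlit LAI tends to 2 cos(theta)
  big <- partition_lai(500, cos(60 * pi / 180), tl_config(clumping = 1))
  expect_equal(big$lai_sunlit, 2 * cos(60 * pi / 180), tolerance = 1e-6)
  # direct evaluation at theta = 30 deg, omega = 0.8, LAI = 2
  p <- partition_lai(2, cos(30 * pi / 180), cfg)
  expect_equal(p$lai_sunlit, 1.0443863633, tolerance = 1e-9)
  expect_equal(p$lai_sunlit + p$lai_shaded, 2)
  # night: all shaded
  pn <- partition_lai(3, -0.1, cfg)
  expect_equal(pn$lai_shaded, 3)
})

test_that("two-leaf APAR matches an independent hand evaluation", {
  cfg <- tl_config(albedo = 0.15, leaf_angle_deg = 60, clumping = 0.8)
  ap <- compute_apar(300, 100, 2, cos(30 * pi / 180), cfg)
  expect_equal(ap$apar_sunlit, 193.7770209657, tolerance = 1e-9)
  expect_equal(ap$apar_shaded, 36.6164288394, tolerance = 1e-9)
  # no PAR: no absorption
  ap0 <- compute_apar(0, 0, 2, 0.7, cfg)
  expect_equal(ap0$apar_sunlit + ap0$apar_shaded, 0)
  # zero canopy absorbs nothing
  apl <- compute_apar(300, 100, 0, 0.7, cfg)
  expect_equal(apl$apar_sunlit + apl$apar_shaded, 0)
  # with no beam and no scattering term, per-leaf irradiance is identical
  cfg2 <- tl_config()
  apd <- compute_apar(0, 200, 3, 0.6, cfg2)
  expect_equal(apd$apar_sunlit / apd$lai_sunlit,
               apd$apar_shaded / apd$lai_shaded, tolerance = 1e-12)
})

test_that("total APAR is monotone in LAI (dense-canopy range) and in PAR", {
  # the multiple-scattering term makes total APAR peak slightly above
  # LAI ~ 5.5 under strong beam radiation; monotonicity holds below that
  cfg <- tl_config()
  lai_grid <- seq(0, 5, by = 0.25)
  tot <- sapply(lai_grid, function(l) {
    a <- compute_apar(300, 100, l, 0.7, cfg)
    a$apar_sunlit + a$apar_shaded
  })
  expect_true(all(diff(tot) >= -1e-10))
  par_grid <- seq(0, 400, by = 20)
  tot2 <- sapply(par_grid, function(p) {
    a <- compute_apar(0.7 * p, 0.3 * p, 3, 0.7, cfg)
    a$apar_sunlit + a$apar_shaded
  })
  expect_true(all(diff(tot2) >= -1e-10))
})

test_that("FPAR-based APAR is the plain product", {
  expect_equal(apar_from_fpar(10, 0.6), 6)
  expect_equal(apar_from_fpar(10, 0), 0)
  expect_equal(apar_from_fpar(10, 1), 10)
  expect_error(apar_from_fpar(10, 1.2), "fpar")
})
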