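# Shared synthetic fixtures, generated once per test run and cached.

tl_test_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(tl_test_cache[[name]])) tl_test_cache[[name]] <- force(expr)
  tl_test_cache[[name]]
}

# Two-year noise-free site with the default seasonal truth.
sim_noise_free <- function() {
  cached_fixture("noise_free_2y", {
    spec <- synthetic_site(years = 2, noise = list(gpp = 0, tc = 0),
                           seed = 11)
    meteo <- generate_meteo(spec)
    lai <- generate_lai_fpar(spec)
    daily <- forward_simulate(spec, meteo, lai)
    prep <- prepare_calibration_data(daily, spec$measurement_height,
                                     spec$canopy_height)
    list(spec = spec, meteo = meteo, lai = lai, daily = prep$data,
         pm = prep$pm, seasons = attr(daily, "seasons"))
  })
}

# Three-year noise-free site (used by the recovery checks).
sim_noise_free_3y <- function() {
  cached_fixture("noise_free_3y", {
    spec <- synthetic_site(years = 3, noise = list(gpp = 0, tc = 0),
                           seed = 21)
    meteo <- generate_meteo(spec)
    daily <- forward_simulate(spec, meteo, generate_lai_fpar(spec))
    prep <- prepare_calibration_data(daily, spec$measurement_height,
                                     spec$canopy_height)
    list(spec = spec, daily = prep$data, pm = prep$pm,
         seasons = attr(daily, "seasons"))
  })
}

# Default noisy three-year site for the experiment design checks.
sim_noisy_3y <- function() {
  cached_fixture("noisy_3y", {
    spec <- synthetic_site(years = 3, seed = 42)
    meteo <- generate_meteo(spec)
    daily <- forward_simulate(spec, meteo, generate_lai_fpar(spec))
    prep <- prepare_calibration_data(daily, spec$measurement_height,
                                     spec$canopy_height)
    list(spec = spec, daily = prep$data, pm = prep$pm,
         seasons = attr(daily, "seasons"))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
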