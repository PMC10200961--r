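# Synthetic flux-tower data: FLUXNET-style half-hourly drivers, 8-day
# LAI/FPAR composites, and daily carbon/water fluxes forward-simulated with
# known seasonally varying physiological parameters. The generator is the
# fixture factory for every downstream test: with zero noise its outputs
# reproduce the model chain exactly.

# Run expr with a temporary RNG seed, restoring global state (internal).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic site specification
#'
#' Describes a synthetic temperate deciduous forest flux site: geometry
#' (latitude, canopy and measurement heights), a phenological LAI curve,
#' sinusoidal meteorology, seasonally varying "true" physiological
#' parameters, and daily observation-noise standard deviations. Defaults
#' emulate a central-European beech site (latitude 51, canopy 23 m,
#' measurement 44 m, annual mean 8.5 degC).
#'
#' @param latitude,longitude site coordinates, degrees.
#' @param canopy_height,measurement_height canopy and sensor heights, m;
#'   the sensor must sit above the canopy.
#' @param years number of simulated 365-day years.
#' @param true_params named list (`spring`, `summer`, `autumn`) of
#'   [parameter_set()] objects; a single `"all"` set is recycled to all
#'   three seasons.
#' @param lai_curve list: `max` (m2 m-2), `greenup`/`senescence` (doy of the
#'   two logistic midpoints), `slope` (days).
#' @param meteo list: `t_mean`/`t_amp`/`t_diurnal` (degC), `transmittance`
#'   (clear-sky), `rh_mean`/`rh_range` (fractions), `wind` (m s-1),
#'   `co2` (umol mol-1).
#' @param noise list: `gpp` (gC m-2 d-1) and `tc` (mm d-1) additive Gaussian
#'   standard deviations at daily scale.
#' @param seed integer RNG seed; identical seeds give identical series.
#' @return List of class `"tl_site"`.
#' @export
synthetic_site <- function(latitude = 51.1, longitude = 10.4,
                           canopy_height = 23, measurement_height = 44,
                           years = 3,
                           true_params = default_true_params(),
                           lai_curve = list(max = 6, greenup = 115,
                                            senescence = 290, slope = 10),
                           meteo = list(t_mean = 8.5, t_amp = 9.5,
                                        t_diurnal = 4, transmittance = 0.75,
                                        rh_mean = 0.74, rh_range = 0.26,
                                        wind = 2.5, co2 = 410),
                           noise = list(gpp = 1.0, tc = 0.2),
                           seed = 42) {
  fail <- function(field, why) stop(sprintf("invalid %s: %s", field, why))
  if (!is.finite(latitude) || abs(latitude) > 90) fail("latitude", "must lie in [-90, 90]")
  if (measurement_height <= canopy_height) {
    fail("measurement_height", "must exceed canopy_height")
  }
  if (years < 1) fail("years", "must be >= 1")
  if (lai_curve$max <= 0) fail("lai_curve$max", "must be positive")
  if (lai_curve$greenup >= lai_curve$senescence) {
    fail("lai_curve", "greenup doy must precede senescence doy")
  }
  if (noise$gpp < 0 || noise$tc < 0) fail("noise", "sds must be >= 0")
  if (meteo$rh_mean <= 0 || meteo$rh_mean > 1) fail("meteo$rh_mean", "must lie in (0, 1]")
  if (inherits(true_params, "tl_params")) {
    true_params <- list(spring = true_params, summer = true_params,
                        autumn = true_params)
  }
  if (!all(c("spring", "summer", "autumn") %in% names(true_params))) {
    fail("true_params", "needs spring, summer and autumn parameter sets")
  }
  structure(list(latitude = latitude, longitude = longitude,
                 canopy_height = canopy_height,
                 measurement_height = measurement_height,
                 years = years, true_params = true_params,
                 lai_curve = lai_curve, meteo = meteo, noise = noise,
                 seed = as.integer(seed)),
            class = "tl_site")
}

#' Default seasonal "true" parameters of the synthetic site
#'
#' Season-specific parameter sets with the contrasts typical of temperate
#' deciduous forests (central-European beech pattern): sunlit maximum LUE
#' peaking in summer (summer/spring ratio 1.5), shaded maximum LUE rising
#' through autumn, and Ball-Berry slopes dipping in summer (g_sh
#' autumn/summer ratio 1.2).
#'
#' @return Named list of [parameter_set()] objects.
#' @export
default_true_params <- function() {
  list(spring = parameter_set(0.50, 3.34, 10, 8.3, "spring"),
       summer = parameter_set(0.75, 4.12, 8, 7.0, "summer"),
       autumn = parameter_set(0.55, 4.74, 9, 8.4, "autumn"))
}

# Double-logistic deciduous LAI phenology (internal).
lai_phenology <- function(doy, curve) {
  curve$max /
    (1 + exp(-(doy - curve$greenup) / curve$slope)) /
    (1 + exp((doy - curve$senescence) / curve$slope))
}

#' Generate half-hourly synthetic meteorology
#'
#' Builds a half-hourly driver series over `spec$years` model years of 365
#' days: a sinusoidal seasonal + diurnal temperature cycle with seeded daily
#' anomalies, clear-sky shortwave scaled by a random daily transmittance,
#' relative humidity in antiphase with the diurnal temperature cycle, VPD
#' consistent with T and RH through the Tetens saturation vapour pressure,
#' constant CO2, and an energy balance (net radiation, ground heat flux,
#' latent/sensible placeholder split) used by the forward simulation.
#' Shortwave is zero whenever the sun is below the horizon.
#'
#' @param spec a [synthetic_site()] specification.
#' @param config a [tl_config()] list.
#' @return Half-hourly data.frame with columns `timestamp` (YYYYMMDDHHMM
#'   start), `date`, `doy`, `hour` (interval midpoint, local solar time),
#'   `sw_in`, `ta`, `rh`, `vpd`, `ws`, `ca`, `le`, `h`, `g`, `p`, `gpp`,
#'   `qc`.
#' @export
generate_meteo <- function(spec, config = tl_config()) {
  n_days <- spec$years * 365L
  day_index <- seq_len(n_days)
  doy_d <- (day_index - 1L) %% 365L + 1L
  dates <- as.Date("2001-01-01") + day_index - 1L
  with_seed(spec$seed, {
    tau_d <- spec$meteo$transmittance * stats::runif(n_days, 0.55, 1)
    t_anom <- stats::rnorm(n_days, 0, 1.5)
    rh_anom <- stats::rnorm(n_days, 0, 0.04)
    ws_anom <- stats::rnorm(n_days, 0, 0.6)
  })
  hh <- rep(seq(0, 23.5, by = 0.5), times = n_days)
  di <- rep(day_index, each = 48L)
  doy <- doy_d[di]
  hour_mid <- hh + 0.25
  m <- spec$meteo
  ta <- m$t_mean - m$t_amp * cos(2 * pi * (doy - 15) / 365) + t_anom[di] +
    0.5 * m$t_diurnal * cos(2 * pi * (hour_mid - 14.5) / 24)
  geo <- solar_zenith(spec$latitude, doy, hour_mid)
  sw <- pmin(extraterrestrial_sw(doy, geo$cos_theta, config) * tau_d[di], 1400)
  sw[geo$cos_theta <= 0] <- 0
  rh <- pmin(1, pmax(0.05, m$rh_mean + rh_anom[di] +
                       0.5 * m$rh_range * cos(2 * pi * (hour_mid - 4) / 24)))
  e_sat <- psychrometrics(ta, config$pressure_kpa, config)$e_sat
  vpd <- e_sat * (1 - rh)
  ws <- pmax(0.2, m$wind + ws_anom[di])
  rn <- 0.8 * sw - 30 * (sw > 0)
  g_soil <- 0.1 * pmax(rn, 0)
  avail <- rn - g_soil
  le <- 0.55 * pmax(avail, 0)
  out <- data.frame(
    timestamp = paste0(format(dates[di], "%Y%m%d"),
                       sprintf("%02d%02d", floor(hh), (hh %% 1) * 60)),
    date = dates[di], doy = doy, hour = hour_mid,
    sw_in = sw, ta = ta, rh = rh, vpd = vpd, ws = ws,
    ca = m$co2, le = le, h = avail - le, g = g_soil, p = 0,
    gpp = 0, qc = 0L
  )
  out
}

#' Generate 8-day LAI and FPAR composites
#'
#' Evaluates the site's double-logistic deciduous LAI curve on the 8-day
#' composite grid (doy 1, 9, ..., 361) of each simulated year and maps LAI
#' to FPAR through a Beer-law absorption model
#' FPAR = 1 - exp(-k LAI), k = `config$k_beer`.
#'
#' @param spec a [synthetic_site()] specification.
#' @param config a [tl_config()] list.
#' @return data.frame with `year`, `doy`, `t` (continuous day over the
#'   record), `lai`, `fpar`.
#' @export
generate_lai_fpar <- function(spec, config = tl_config()) {
  grid <- expand.grid(doy = seq(1L, 361L, by = 8L),
                      year = seq_len(spec$years))
  lai <- lai_phenology(grid$doy, spec$lai_curve)
  data.frame(year = grid$year, doy = grid$doy,
             t = (grid$year - 1L) * 365L + grid$doy,
             lai = lai, fpar = 1 - exp(-config$k_beer * lai))
}

#' Forward-simulate daily fluxes with known parameters
#'
#' Runs the full model chain (daytime screening, daily aggregation,
#' LAI/FPAR interpolation, two-leaf radiation, GPP, Ball-Berry conductance,
#' Penman-Monteith transpiration) on the synthetic drivers with the site's
#' true seasonal parameters, then adds daily Gaussian observation noise and
#' derives observed ET from noisy Tc through a fixed synthetic T/ET ratio
#' schedule (0.45 + 0.3 FPAR) so the uWUE partitioning step has signal to
#' recover. Seasons are identified from the simulated temperature itself,
#' so calibration on the same data sees the same windows. Truth columns are
#' stored alongside the noisy observations.
#'
#' @param spec a [synthetic_site()] specification.
#' @param meteo half-hourly series from [generate_meteo()].
#' @param lai_fpar composite series from [generate_lai_fpar()].
#' @param config a [tl_config()] list.
#' @return Daily data.frame with drivers (`ta`, `rh`, `vpd`, `ws`, `ca`,
#'   `par_mj`, `a_mj`, `lai`, `fpar`, `apar_sunlit`, `apar_shaded`,
#'   `f_vpd`, `f_t`, `daytime_s`, `season`), truth (`gpp_su_true`,
#'   `gpp_sh_true`, `gpp_true`, `gs_true`, `tc_true`) and observations
#'   (`gpp_obs`, `tc_obs`, `et_obs`). The season windows are attached as
#'   attribute `"seasons"`.
#' @export
forward_simulate <- function(spec, meteo, lai_fpar, config = tl_config()) {
  records <- qc_filter_daytime(meteo, config)
  daily <- aggregate_daily(records, config)
  lai_daily <- interpolate_lai_fpar(
    data.frame(t = lai_fpar$t, lai = lai_fpar$lai, fpar = lai_fpar$fpar),
    t_out = seq_len(spec$years * 365L), config = config)
  lai_daily$date <- as.Date("2001-01-01") + lai_daily$t - 1L
  idx <- match(daily$date, lai_daily$date)
  if (anyNA(idx)) stop("meteo and LAI series are misaligned in time")
  daily$lai <- lai_daily$lai[idx]
  daily$fpar <- lai_daily$fpar[idx]
  rad <- canopy_radiation_daily(records, lai_daily[, c("date", "lai")],
                                spec$latitude, config)
  ri <- match(daily$date, rad$date)
  daily$apar_sunlit <- rad$apar_sunlit[ri]
  daily$apar_shaded <- rad$apar_shaded[ri]
  daily$f_vpd <- f_vpd(daily$vpd, config)
  daily$f_t <- f_temp(daily$ta, config)
  seasons <- identify_seasons(daily, config)
  daily$season <- season_of_doy(daily$doy, seasons)
  # Out-of-season days carry the nearest season's physiology; LAI is near
  # zero there so the choice is inconsequential.
  eff <- daily$season
  eff[is.na(eff) & daily$doy < seasons$summer[1]] <- "spring"
  eff[is.na(eff)] <- "autumn"
  pget <- function(field) {
    vapply(eff, function(s) spec$true_params[[s]][[field]], numeric(1))
  }
  g <- estimate_gpp(daily$apar_sunlit, daily$apar_shaded,
                    daily$f_vpd, daily$f_t,
                    list(eps_msu = pget("eps_msu"), eps_msh = pget("eps_msh")))
  daily$gpp_su_true <- g$gpp_sunlit
  daily$gpp_sh_true <- g$gpp_shaded
  daily$gpp_true <- g$gpp
  rate_su <- gpp_daily_to_molar_rate(g$gpp_sunlit, daily$daytime_s, config)
  rate_sh <- gpp_daily_to_molar_rate(g$gpp_shaded, daily$daytime_s, config)
  daily$gs_true <- canopy_conductance(rate_su, rate_sh, daily$rh, daily$ca,
                                      list(g_su = pget("g_su"),
                                           g_sh = pget("g_sh")),
                                      config)
  pm <- pm_inputs(daily, spec$measurement_height, spec$canopy_height, config)
  daily$tc_true <- penman_monteith_tc(pm, daily$gs_true)
  n <- nrow(daily)
  with_seed(spec$seed + 1L, {
    daily$gpp_obs <- daily$gpp_true + stats::rnorm(n, 0, spec$noise$gpp)
    daily$tc_obs <- daily$tc_true + stats::rnorm(n, 0, spec$noise$tc)
  })
  ratio <- 0.45 + 0.3 * daily$fpar
  daily$et_obs <- pmax(daily$tc_obs, 0) / ratio
  attr(daily, "seasons") <- seasons
  daily
}

#' Embed daily fluxes into the half-hourly series
#'
#' Distributes the daily observed GPP and ET back into the half-hourly GPP
#' and latent-heat columns, proportionally to shortwave irradiance over the
#' retained daytime records, so that daily aggregation of the written
#' FLUXNET-style file reproduces the daily observations exactly. Sensible
#' heat is adjusted to keep LE + H (available energy) unchanged.
#'
#' @param meteo half-hourly series from [generate_meteo()].
#' @param daily forward-simulated daily series ([forward_simulate()]).
#' @param config a [tl_config()] list.
#' @param step_s timestep, seconds.
#' @return `meteo` with `gpp`, `le`, `h` filled in.
#' @export
embed_fluxes <- function(meteo, daily, config = tl_config(), step_s = 1800) {
  avail <- meteo$le + meteo$h
  meteo$gpp <- 0
  meteo$le <- 0
  keep <- !is.na(meteo$sw_in) & meteo$sw_in > config$sw_threshold
  lambda_day <- psychrometrics(daily$ta, config$pressure_kpa, config)$lambda
  groups <- split(which(keep), as.character(meteo$date[keep]))
  for (i in seq_len(nrow(daily))) {
    sel <- groups[[as.character(daily$date[i])]]
    if (is.null(sel) || !length(sel)) next
    w <- meteo$sw_in[sel] / sum(meteo$sw_in[sel])
    meteo$gpp[sel] <- daily$gpp_obs[i] * w /
      (config$molar_mass_c * 1e-6 * step_s)
    meteo$le[sel] <- daily$et_obs[i] * lambda_day[i] * 1e6 * w / step_s
  }
  meteo$h <- avail - meteo$le
  meteo
}

# FLUXNET FULLSET dialect: internal column -> file column, with unit
# conversion on RH (fraction <-> percent) and VPD (kPa <-> hPa).
fluxnet_columns <- c(sw_in = "SW_IN_F", ta = "TA_F", rh = "RH",
                     vpd = "VPD_F", ws = "WS_F", ca = "CO2_F_MDS",
                     le = "LE_F_MDS", h = "H_F_MDS", g = "G_F_MDS",
                     p = "P_F", gpp = "GPP_DT_VUT_REF", qc = "NEE_VUT_REF_QC")

#' Write half-hourly records as a FLUXNET2015-style CSV
#'
#' Uses the FULLSET column dialect (`TIMESTAMP_START`/`TIMESTAMP_END` in
#' YYYYMMDDHHMM, `SW_IN_F`, `TA_F`, `RH` in percent, `VPD_F` in hPa,
#' `GPP_DT_VUT_REF`, ...) with missing values encoded as -9999.
#'
#' @param records half-hourly data.frame in internal units.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(records, path) {
  if (nrow(records) == 0) stop("no records to write")
  out <- data.frame(TIMESTAMP_START = records$timestamp)
  end <- as.POSIXct(records$timestamp, format = "%Y%m%d%H%M", tz = "UTC") +
    1800
  out$TIMESTAMP_END <- format(end, "%Y%m%d%H%M")
  for (nm in names(fluxnet_columns)) {
    v <- records[[nm]]
    if (nm == "rh") v <- v * 100
    if (nm == "vpd") v <- v * 10
    v[!is.finite(v)] <- -9999
    out[[fluxnet_columns[[nm]]]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FLUXNET2015-style CSV into internal half-hourly records
#'
#' Name-based parsing (column order is irrelevant); -9999 becomes NA; RH
#' and VPD are converted back to fraction and kPa. Date, day of year and
#' interval-midpoint hour are derived from `TIMESTAMP_START`.
#'
#' @param path CSV path.
#' @return Half-hourly data.frame in internal units.
#' @export
read_fluxnet_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = TRUE)
  ts <- as.character(raw$TIMESTAMP_START)
  out <- data.frame(timestamp = ts,
                    date = as.Date(substr(ts, 1, 8), format = "%Y%m%d"))
  out$doy <- as.integer(format(out$date, "%j"))
  out$hour <- as.numeric(substr(ts, 9, 10)) +
    as.numeric(substr(ts, 11, 12)) / 60 + 0.25
  for (nm in names(fluxnet_columns)) {
    v <- raw[[fluxnet_columns[[nm]]]]
    if (is.null(v)) {
      out[[nm]] <- NA_real_
      next
    }
    v[v == -9999] <- NA
    if (nm == "rh") v <- v / 100
    if (nm == "vpd") v <- v / 10
    out[[nm]] <- v
  }
  out
}

#' Write / read the 8-day LAI-FPAR composite CSV
#'
#' @param series data.frame from [generate_lai_fpar()].
#' @param path CSV path.
#' @return `path` (write) or the parsed data.frame (read).
#' @export
write_lai_csv <- function(series, path) {
  utils::write.csv(series[, c("year", "doy", "t", "lai", "fpar")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lai_csv
#' @export
read_lai_csv <- function(path) {
  utils::read.csv(path)
}
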