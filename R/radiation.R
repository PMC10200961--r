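# Canopy radiation: solar geometry, direct/diffuse PAR partitioning, and the
# two-leaf sunlit/shaded LAI and APAR computation. All per-timestep functions
# are vectorized; daily APAR is an integral of half-hourly values because the
# zenith-dependent terms cannot be computed from daily means without bias.

#' Solar declination
#'
#' @param doy day of year (1-366).
#' @return Declination in radians (Cooper's formula).
#' @export
solar_declination <- function(doy) {
  23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
}

#' Solar zenith angle
#'
#' Standard declination / hour-angle geometry. `hour` is local solar time in
#' decimal hours, so solar noon is at hour 12 exactly.
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param doy day of year.
#' @param hour local solar time, decimal hours.
#' @return A data.frame with columns `cos_theta`, `theta` (radians) and
#'   `daylight` (logical, `cos_theta > 0`).
#' @export
#' @examples
#' solar_zenith(0, 80, 12) # equator, equinox, noon: theta ~ 0
solar_zenith <- function(latitude, doy, hour) {
  if (any(latitude < -90 | latitude > 90)) {
    stop("latitude must lie in [-90, 90]")
  }
  lat <- latitude * pi / 180
  decl <- solar_declination(doy)
  ha <- (hour - 12) * pi / 12
  cos_theta <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_theta <- pmin(1, pmax(-1, cos_theta))
  data.frame(cos_theta = cos_theta, theta = acos(cos_theta),
             daylight = cos_theta > 0)
}

#' Eccentricity-corrected extraterrestrial irradiance on a horizontal plane
#'
#' @param doy day of year.
#' @param cos_theta cosine of the solar zenith angle.
#' @param config a [tl_config()] list.
#' @return W m-2; zero when the sun is below the horizon.
#' @export
extraterrestrial_sw <- function(doy, cos_theta, config = tl_config()) {
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  config$solar_constant * e0 * pmax(cos_theta, 0)
}

#' PAR from shortwave irradiance
#'
#' PAR is taken as a fixed fraction (default 0.45) of incoming shortwave,
#' at whatever time resolution the input has.
#'
#' @param sw_in incoming shortwave, W m-2 (or MJ m-2 per step).
#' @param config a [tl_config()] list.
#' @return PAR in the same units as `sw_in`.
#' @export
par_from_shortwave <- function(sw_in, config = tl_config()) {
  if (any(sw_in < 0, na.rm = TRUE)) stop("sw_in must be non-negative")
  config$par_sw_fraction * sw_in
}

#' Split PAR into direct and diffuse components
#'
#' The diffuse fraction is a configurable polynomial in the clearness index
#' R = SW / (S0 * E0 * cos(theta)), clipped to `config$diffuse_range`
#' (default \[0.1, 1\]); the direct beam is the remainder, so the two
#' components always sum to PAR exactly. When the sun is below the horizon
#' all components are zero.
#'
#' @param par PAR, W m-2.
#' @param sw_in incoming shortwave, W m-2 (clearness-index numerator).
#' @param doy day of year.
#' @param cos_theta cosine of solar zenith.
#' @param config a [tl_config()] list.
#' @return data.frame with `par`, `par_dir`, `par_dif`, `clearness`.
#' @export
split_direct_diffuse <- function(par, sw_in, doy, cos_theta,
                                 config = tl_config()) {
  n <- length(par)
  toa <- extraterrestrial_sw(doy, cos_theta, config)
  clearness <- ifelse(toa > 0, pmin(sw_in / toa, 1), 0)
  fdif <- diffuse_fraction(clearness, config)
  night <- cos_theta <= 0
  par_eff <- ifelse(night, 0, par)
  par_dif <- fdif * par_eff
  par_dir <- par_eff - par_dif
  data.frame(par = par_eff, par_dir = par_dir, par_dif = par_dif,
             clearness = clearness)
}

#' Diffuse PAR fraction from the clearness index
#'
#' @param clearness clearness index R in \[0, 1\].
#' @param config a [tl_config()] list; `diffuse_coefs` are ascending-power
#'   polynomial coefficients, `diffuse_range` the clipping interval.
#' @return Diffuse fraction in `config$diffuse_range`.
#' @export
diffuse_fraction <- function(clearness, config = tl_config()) {
  co <- config$diffuse_coefs
  f <- rep(0, length(clearness))
  for (i in seq_along(co)) f <- f + co[i] * clearness^(i - 1)
  pmin(config$diffuse_range[2], pmax(config$diffuse_range[1], f))
}

#' Sunlit/shaded partition of leaf area index
#'
#' LAI_sunlit = 2 cos(theta) * (1 - exp(-0.5 * Omega * LAI / cos(theta)));
#' LAI_shaded is the exact remainder, floored at zero. At night the whole
#' canopy is shaded.
#'
#' @param lai_tot total LAI, m2 m-2 (>= 0).
#' @param cos_theta cosine of solar zenith.
#' @param config a [tl_config()] list (clumping index `clumping`).
#' @return data.frame with `lai_sunlit`, `lai_shaded`.
#' @export
#' @examples
#' partition_lai(2, cos(30 * pi / 180), tl_config(clumping = 0.8))
partition_lai <- function(lai_tot, cos_theta, config = tl_config()) {
  if (any(lai_tot < 0, na.rm = TRUE)) stop("lai_tot must be non-negative")
  om <- config$clumping
  if (om <= 0 || om > 1) stop("clumping index must lie in (0, 1]")
  day <- cos_theta > 0
  lai_su <- ifelse(day,
                   2 * cos_theta * (1 - exp(-0.5 * om * lai_tot /
                                              pmax(cos_theta, 1e-12))),
                   0)
  lai_su <- pmin(lai_su, lai_tot)
  data.frame(lai_sunlit = lai_su, lai_shaded = lai_tot - lai_su)
}

#' Two-leaf absorbed PAR
#'
#' Per-timestep absorbed PAR of the sunlit and shaded leaf classes:
#' \deqn{APAR_{su} = (1-\alpha)\,[PAR_{dir}\cos\beta/\cos\theta +
#'   (PAR_{dif}-PAR_{dif,u})/LAI + C]\,LAI_{su}}
#' \deqn{APAR_{sh} = (1-\alpha)\,[(PAR_{dif}-PAR_{dif,u})/LAI + C]\,LAI_{sh}}
#' where the below-canopy diffuse flux is
#' PAR_dif,u = PAR_dif * exp(-0.5 Omega LAI / cos(theta_bar)) with a
#' representative zenith theta_bar for diffuse transmission, and the
#' multiple-scattering contribution per unit leaf area is
#' C = 0.07 Omega PAR_dir (1.1 - 0.1 LAI) exp(-cos(theta)), floored at 0.
#' The beam ratio cos(beta)/cos(theta) is capped near sunrise/sunset.
#'
#' @param par_dir,par_dif direct and diffuse PAR, W m-2.
#' @param lai_tot total LAI, m2 m-2.
#' @param cos_theta cosine of solar zenith.
#' @param config a [tl_config()] list.
#' @return data.frame with `apar_sunlit`, `apar_shaded` (same units as PAR)
#'   and the LAI partition.
#' @export
compute_apar <- function(par_dir, par_dif, lai_tot, cos_theta,
                         config = tl_config()) {
  alpha <- config$albedo
  beta <- config$leaf_angle_deg * pi / 180
  om <- config$clumping
  lp <- partition_lai(lai_tot, cos_theta, config)
  day <- cos_theta > 0 & lai_tot > 0
  cos_tbar <- cos(config$theta_bar_deg * pi / 180)
  par_dif_u <- par_dif * exp(-0.5 * om * lai_tot / cos_tbar)
  cterm <- pmax(0.07 * om * par_dir * (1.1 - 0.1 * lai_tot) *
                  exp(-pmax(cos_theta, 0)), 0)
  shared <- ifelse(day, (par_dif - par_dif_u) / pmax(lai_tot, 1e-12) + cterm, 0)
  beam_ratio <- pmin(cos(beta) / pmax(cos_theta, 1e-12),
                     config$beam_ratio_max)
  apar_su <- ifelse(day,
                    (1 - alpha) * (par_dir * beam_ratio + shared) *
                      lp$lai_sunlit,
                    0)
  apar_sh <- ifelse(day, (1 - alpha) * shared * lp$lai_shaded, 0)
  data.frame(apar_sunlit = pmax(apar_su, 0), apar_shaded = pmax(apar_sh, 0),
             lai_sunlit = lp$lai_sunlit, lai_shaded = lp$lai_shaded)
}

#' APAR from the FPAR product
#'
#' The satellite-style alternative to the two-leaf APAR: the product of PAR
#' and the fraction of absorbed PAR.
#'
#' @param par PAR (typically daily MJ m-2 d-1).
#' @param fpar fraction of absorbed PAR in \[0, 1\].
#' @return APAR in the units of `par`.
#' @export
apar_from_fpar <- function(par, fpar) {
  if (any(fpar < 0 | fpar > 1, na.rm = TRUE)) stop("fpar must lie in [0, 1]")
  par * fpar
}

#' Daily two-leaf canopy radiation from half-hourly records
#'
#' Runs the solar-geometry, PAR-partitioning and two-leaf APAR chain at the
#' native half-hourly resolution and integrates to daily totals
#' (MJ m-2 d-1). Input records must already be daytime-screened.
#'
#' @param records data.frame of half-hourly records with columns `date`,
#'   `doy`, `hour`, `sw_in`; a `lai` column is taken from `records` or joined
#'   from `lai_daily`.
#' @param lai_daily optional data.frame with columns `date`, `lai`, `fpar`
#'   giving daily LAI/FPAR to join on date.
#' @param latitude site latitude, degrees north.
#' @param config a [tl_config()] list.
#' @param step_s timestep length, seconds (1800).
#' @return data.frame with one row per day: `date`, `apar_sunlit`,
#'   `apar_shaded`, `apar_tl`, `par_mj` (all MJ m-2 d-1) and daytime-mean
#'   `lai_sunlit`, `lai_shaded`.
#' @export
canopy_radiation_daily <- function(records, lai_daily = NULL, latitude,
                                   config = tl_config(), step_s = 1800) {
  if (!is.null(lai_daily)) {
    idx <- match(records$date, lai_daily$date)
    records$lai <- lai_daily$lai[idx]
  }
  if (is.null(records$lai)) stop("records need a 'lai' column or lai_daily")
  geo <- solar_zenith(latitude, records$doy, records$hour)
  par_w <- par_from_shortwave(records$sw_in, config)
  sp <- split_direct_diffuse(par_w, records$sw_in, records$doy,
                             geo$cos_theta, config)
  ap <- compute_apar(sp$par_dir, sp$par_dif, records$lai, geo$cos_theta,
                     config)
  to_mj <- step_s * 1e-6
  agg <- function(x, f) as.numeric(tapply(x, records$date, f))
  out <- data.frame(
    date = sort(unique(records$date)),
    apar_sunlit = agg(ap$apar_sunlit * to_mj, sum),
    apar_shaded = agg(ap$apar_shaded * to_mj, sum),
    par_mj = agg(par_w * to_mj, sum),
    lai_sunlit = agg(ap$lai_sunlit, mean),
    lai_shaded = agg(ap$lai_shaded, mean)
  )
  out$apar_tl <- out$apar_sunlit + out$apar_shaded
  out
}
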