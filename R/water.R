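# Water-flux module: psychrometrics, wet-surface fraction, aerodynamic and
# canopy conductance, the Penman-Monteith transpiration equation, and its
# algebraic inversion for a reference canopy conductance.
#
# Unit conventions: conductances are carried in molar units (mol m-2 s-1)
# and converted to m s-1 inside the Penman-Monteith evaluation via the molar
# density of air; energies are daily MJ m-2 d-1; VPD is kPa; transpiration
# is mm d-1 (1 mm = 1 kg water m-2).

#' Psychrometric quantities
#'
#' FAO-56 forms: Tetens saturation vapour pressure and its slope, linear
#' latent heat of vaporization, psychrometric constant, and ideal-gas air
#' densities (mass and molar).
#'
#' @param t_air air temperature, degC (plausible range -40 to 50).
#' @param pressure_kpa air pressure, kPa.
#' @param config a [tl_config()] list (specific heat `cp`).
#' @return data.frame with columns `e_sat` (kPa), `s` (kPa degC-1),
#'   `lambda` (MJ kg-1), `gamma` (kPa degC-1), `rho` (kg m-3),
#'   `rho_mol` (mol m-3).
#' @export
#' @examples
#' psychrometrics(20)
psychrometrics <- function(t_air, pressure_kpa = 101.3,
                           config = tl_config()) {
  if (any(t_air < -40 | t_air > 50, na.rm = TRUE)) {
    warning("t_air outside the plausible range (-40, 50) degC")
  }
  e_sat <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  s <- 4098 * e_sat / (t_air + 237.3)^2
  lambda <- 2.501 - 0.002361 * t_air
  gamma <- config$cp * pressure_kpa / (0.622 * lambda)
  t_k <- t_air + 273.15
  rho <- pressure_kpa * 1000 / (287.05 * t_k)
  rho_mol <- pressure_kpa * 1000 / (8.314 * t_k)
  data.frame(e_sat = e_sat, s = s, lambda = lambda, gamma = gamma,
             rho = rho, rho_mol = rho_mol)
}

#' Wet-surface fraction
#'
#' Zero for relative humidity below 0.70 and RH^4 above, following the
#' MOD16-style wet-canopy formulation.
#'
#' @param rh relative humidity as a fraction in \[0, 1\].
#' @return Fraction in \[0, 1\], vectorized.
#' @export
#' @examples
#' fwet(c(0.5, 0.8, 1))
fwet <- function(rh) {
  if (any(rh < 0 | rh > 1, na.rm = TRUE)) stop("rh must lie in [0, 1]")
  ifelse(rh < 0.70, 0, rh^4)
}

#' Aerodynamic conductance from the neutral wind log-profile
#'
#' g_a = k^2 u / \[ln((Z - d)/z0)\]^2 in m s-1 with displacement height
#' d = 0.67 H and roughness length z0 = 0.1 H, converted to molar units via
#' the molar density of air. No stability correction is applied.
#'
#' @param wind wind speed at measurement height, m s-1.
#' @param z measurement height, m.
#' @param h canopy height, m (must satisfy z - 0.67 h > 0.1 h).
#' @param t_air air temperature, degC (for the molar density).
#' @param pressure_kpa air pressure, kPa.
#' @param config a [tl_config()] list.
#' @return Aerodynamic conductance, mol m-2 s-1; floored at `config$ga_min`
#'   for non-positive wind.
#' @export
#' @examples
#' aerodynamic_conductance(3, z = 44, h = 23, t_air = 15)
aerodynamic_conductance <- function(wind, z, h, t_air = 15,
                                    pressure_kpa = 101.3,
                                    config = tl_config()) {
  d <- config$d_frac * h
  z0 <- config$z0_frac * h
  if (z - d <= z0) stop("invalid geometry: z - d must exceed z0")
  log_term <- log((z - d) / z0)
  ga_ms <- config$karman^2 * pmax(wind, 0) / log_term^2
  rho_mol <- psychrometrics(t_air, pressure_kpa, config)$rho_mol
  pmax(ga_ms * rho_mol, config$ga_min)
}

#' Two-leaf Ball-Berry canopy conductance
#'
#' G_s = g_sh GPP_shaded RH / Ca + g_su GPP_sunlit RH / Ca + G_s,min with
#' assimilation rates in umol CO2 m-2 s-1 and Ca in umol mol-1, so the
#' slope terms are dimensionless multiples of mol m-2 s-1; the soil-surface
#' minimum conductance G_s,min = 0.001 mol m-2 s-1 is the intercept.
#'
#' @param gpp_su_rate,gpp_sh_rate sunlit/shaded assimilation rates,
#'   umol CO2 m-2 s-1.
#' @param rh relative humidity fraction.
#' @param ca ambient CO2, umol mol-1 (> 0).
#' @param params a [parameter_set()] (fields `g_su`, `g_sh` used).
#' @param config a [tl_config()] list (`gs_min`).
#' @return Canopy conductance, mol m-2 s-1.
#' @export
#' @examples
#' p <- parameter_set(0.75, 3.05, 10, 8, "summer")
#' canopy_conductance(10, 5, 0.6, 400, p)
canopy_conductance <- function(gpp_su_rate, gpp_sh_rate, rh, ca, params,
                               config = tl_config()) {
  if (any(ca <= 0, na.rm = TRUE)) stop("ca must be positive")
  params$g_sh * gpp_sh_rate * rh / ca +
    params$g_su * gpp_su_rate * rh / ca +
    config$gs_min
}

#' Assemble Penman-Monteith inputs from daily data
#'
#' Builds the conductance-independent part of the Penman-Monteith equation
#' from daytime-mean states and daytime-integrated energy: psychrometrics at
#' the daily mean temperature, canopy-allocated available energy
#' A_c = A * FPAR, wet fraction from daily RH, and the aerodynamic
#' conductance from daily wind.
#'
#' @param daily data.frame with columns `ta`, `rh`, `vpd`, `ws`, `a_mj`
#'   (available energy, MJ m-2 d-1), `fpar`, `daytime_s`.
#' @param z,h measurement and canopy heights, m.
#' @param config a [tl_config()] list.
#' @return data.frame of class `"tl_pm"` with the per-day P-M inputs.
#' @export
pm_inputs <- function(daily, z, h, config = tl_config()) {
  psy <- psychrometrics(daily$ta, config$pressure_kpa, config)
  ga <- aerodynamic_conductance(daily$ws, z, h, daily$ta,
                                config$pressure_kpa, config)
  out <- data.frame(
    s = psy$s, lambda = psy$lambda, gamma = psy$gamma,
    rho = psy$rho, rho_mol = psy$rho_mol,
    a_c = daily$a_mj * daily$fpar,
    f_wet = fwet(daily$rh),
    ga = ga, vpd = daily$vpd, fpar = daily$fpar,
    daytime_s = daily$daytime_s, cp = config$cp
  )
  class(out) <- c("tl_pm", "data.frame")
  out
}

# Shared numerator/denominator pieces of the P-M form (internal).
pm_numerator <- function(pm) {
  ga_ms <- pm$ga / pm$rho_mol
  (pm$s * pm$a_c +
     pm$rho * pm$cp * pm$fpar * pm$vpd * ga_ms * pm$daytime_s) *
    (1 - pm$f_wet)
}

#' Penman-Monteith canopy transpiration
#'
#' \deqn{\lambda E_c = \frac{[s A_c + \rho C_p\, FPAR\, VPD\, G_a']
#'   (1 - F_{wet})}{s + \gamma (1 + G_a / G_s)}}
#' with the aerodynamic term integrated over the daytime, and
#' Tc = lambda E_c / lambda in mm d-1, floored at zero. The conductance
#' ratio G_a/G_s is unit-free, so molar conductances can be used directly
#' in the denominator; the numerator converts G_a to m s-1 via the molar
#' density of air.
#'
#' @param pm a [pm_inputs()] frame.
#' @param gs canopy conductance, mol m-2 s-1 (> 0).
#' @return Transpiration, mm d-1.
#' @export
penman_monteith_tc <- function(pm, gs) {
  if (any(gs <= 0, na.rm = TRUE)) stop("gs must be positive")
  num <- pm_numerator(pm)
  den <- pm$s + pm$gamma * (1 + pm$ga / gs)
  pmax(num / den / pm$lambda, 0)
}

#' Invert the Penman-Monteith equation for canopy conductance
#'
#' Algebraic inversion of [penman_monteith_tc()]: given an observed Tc, the
#' reference G_s is \eqn{\gamma G_a / (N(1-F_{wet})/(\lambda T_c) - s -
#' \gamma)}. Days where Tc reaches or exceeds the energy-limited asymptote
#' (G_s to infinity) are non-invertible and returned as NA; Tc <= 0 maps to
#' NA as a boundary flag.
#'
#' @param pm a [pm_inputs()] frame.
#' @param tc observed transpiration, mm d-1.
#' @return Reference canopy conductance, mol m-2 s-1, with NA flags for
#'   boundary and non-invertible days.
#' @export
invert_pm_for_gs <- function(pm, tc) {
  num <- pm_numerator(pm)
  e <- tc * pm$lambda
  x <- num / e - pm$s - pm$gamma
  gs <- ifelse(tc > 0 & x > 0 & pm$f_wet < 1, pm$gamma * pm$ga / x, NA_real_)
  gs
}
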