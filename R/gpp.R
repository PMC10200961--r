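# Two-leaf light-use-efficiency GPP model with VPD and temperature scalars.

#' Vapour-pressure-deficit limiting scalar
#'
#' MOD17-style linear ramp: 1 at or below `vpd_open`, 0 at or above
#' `vpd_close`, linear in between.
#'
#' @param vpd vapour pressure deficit, kPa (>= 0).
#' @param config a [tl_config()] list with `vpd_open`, `vpd_close` (kPa).
#' @return Scalar in \[0, 1\], vectorized.
#' @export
f_vpd <- function(vpd, config = tl_config()) {
  lo <- config$vpd_open
  hi <- config$vpd_close
  pmin(1, pmax(0, (hi - vpd) / (hi - lo)))
}

#' Temperature limiting scalar (TEM form)
#'
#' f(T) = (T - Tmin)(T - Tmax) / \[(T - Tmin)(T - Tmax) - (T - Topt)^2\],
#' clipped to \[0, 1\] and zero outside \[Tmin, Tmax\]. Unlike the pure
#' low-temperature ramp of MOD17 this form also suppresses photosynthesis at
#' high temperature.
#'
#' @param t_air air temperature, degC.
#' @param config a [tl_config()] list with cardinal temperatures `t_min`,
#'   `t_opt`, `t_max`.
#' @return Scalar in \[0, 1\], vectorized.
#' @export
f_temp <- function(t_air, config = tl_config()) {
  tmin <- config$t_min; topt <- config$t_opt; tmax <- config$t_max
  num <- (t_air - tmin) * (t_air - tmax)
  den <- num - (t_air - topt)^2
  f <- ifelse(abs(den) < 1e-12, 0, num / den)
  f[t_air <= tmin | t_air >= tmax] <- 0
  pmin(1, pmax(0, f))
}

#' Two-leaf GPP
#'
#' GPP_sunlit = eps_msu * APAR_sunlit * f(VPD) * f(T), GPP_shaded analogous
#' with eps_msh, and total GPP is their sum.
#'
#' @param apar_sunlit,apar_shaded daily absorbed PAR, MJ m-2 d-1.
#' @param fv,ft humidity and temperature scalars in \[0, 1\]
#'   (see [f_vpd()], [f_temp()]).
#' @param params a [parameter_set()] (or any list with `eps_msu`, `eps_msh`).
#' @return data.frame with `gpp_sunlit`, `gpp_shaded`, `gpp` in gC m-2 d-1.
#' @export
#' @examples
#' p <- parameter_set(0.75, 3.05, 10, 8, "summer")
#' estimate_gpp(4, 2, 0.8, 0.9, p)
estimate_gpp <- function(apar_sunlit, apar_shaded, fv, ft, params) {
  if (any(fv < 0 | fv > 1, na.rm = TRUE) || any(ft < 0 | ft > 1, na.rm = TRUE)) {
    stop("limiting scalars must lie in [0, 1]")
  }
  gs_u <- params$eps_msu * apar_sunlit * fv * ft
  gs_h <- params$eps_msh * apar_shaded * fv * ft
  data.frame(gpp_sunlit = gs_u, gpp_shaded = gs_h, gpp = gs_u + gs_h)
}

#' Convert daily GPP to a mean daytime molar assimilation rate
#'
#' Inverse of the daily aggregation unit conversion: divides gC m-2 d-1 by
#' the molar mass of carbon and the daytime duration.
#'
#' @param gpp_daily gC m-2 d-1.
#' @param daytime_s daytime duration, seconds (> 0).
#' @param config a [tl_config()] list.
#' @return Assimilation rate, umol CO2 m-2 s-1.
#' @export
gpp_daily_to_molar_rate <- function(gpp_daily, daytime_s,
                                    config = tl_config()) {
  if (any(daytime_s <= 0, na.rm = TRUE)) stop("daytime_s must be positive")
  gpp_daily / (config$molar_mass_c * 1e-6 * daytime_s)
}
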