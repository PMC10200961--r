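#' Model configuration
#'
#' Collects every physical constant and tunable threshold of the model chain
#' in one list so that the same settings flow through the synthetic-data
#' generator, the forward model and the calibration, and so that any of them
#' can be swept in sensitivity analyses.
#'
#' @param ... name-value overrides of the defaults listed below. Unknown
#'   names raise an error.
#'
#' @details Defaults, with units:
#' \describe{
#'   \item{par_sw_fraction}{PAR fraction of shortwave irradiance (0.45).}
#'   \item{solar_constant}{Top-of-atmosphere solar irradiance, W m-2 (1361).}
#'   \item{albedo}{Canopy PAR albedo \eqn{\alpha} (0.15).}
#'   \item{leaf_angle_deg}{Representative leaf angle \eqn{\beta}, degrees
#'     (60, a spherical leaf-angle-distribution proxy).}
#'   \item{clumping}{Clumping index \eqn{\Omega} (0.8, deciduous broadleaf).}
#'   \item{diffuse_coefs}{Quartic polynomial coefficients (ascending powers)
#'     mapping the clearness index to the diffuse PAR fraction; Erbs-style
#'     default.}
#'   \item{diffuse_range}{Clipping range of the diffuse fraction (c(0.1, 1)).}
#'   \item{theta_bar_deg}{Representative zenith angle for diffuse
#'     transmission through the canopy, degrees (57.5).}
#'   \item{beam_ratio_max}{Cap on cos(beta)/cos(theta) near sunrise/sunset (10).}
#'   \item{k_beer}{Beer-law extinction coefficient used by the synthetic
#'     LAI-to-FPAR mapping (0.5).}
#'   \item{vpd_open, vpd_close}{VPD ramp thresholds of the humidity scalar,
#'     kPa (0.65, 2.5).}
#'   \item{t_min, t_opt, t_max}{Temperature-scalar cardinal temperatures,
#'     degC (-1, 25, 40).}
#'   \item{gs_min}{Minimum surface conductance, mol m-2 s-1 (0.001).}
#'   \item{gs_ref_max}{Plausibility cap on the reference conductance
#'     inverted from observed transpiration, mol m-2 s-1 (2); inversions
#'     above it sit on the flat flank of the Penman-Monteith curve where
#'     noise in Tc maps to unbounded conductance, and are flagged NA.}
#'   \item{pm_invert_max_frac}{Well-conditioned inversion screen: observed
#'     Tc above this fraction (0.7) of the day's energy-limited asymptote
#'     is treated as non-invertible, because the error amplification of the
#'     inversion diverges at the asymptote.}
#'   \item{karman, d_frac, z0_frac}{von Karman constant (0.41), displacement
#'     height fraction of canopy height (0.67), roughness length fraction
#'     (0.1) for the neutral log-profile aerodynamic conductance.}
#'   \item{ga_min}{Floor on aerodynamic conductance, mol m-2 s-1 (0.001).}
#'   \item{pressure_kpa}{Surface air pressure, kPa (101.3).}
#'   \item{cp}{Specific heat of air at constant pressure, MJ kg-1 degC-1
#'     (1.013e-3).}
#'   \item{sw_threshold}{Daytime shortwave screening threshold, W m-2 (5);
#'     records are retained only when SW_IN strictly exceeds it.}
#'   \item{qc_max}{Highest acceptable quality flag (1 = measured or good
#'     gap-fill).}
#'   \item{sg_window, sg_order}{Savitzky-Golay window length in days (15,
#'     odd) and polynomial order (2) for LAI/FPAR smoothing.}
#'   \item{season_smooth_days}{Running-mean window (days) applied to the
#'     multi-year mean temperature curve before percentile thresholding (15).}
#'   \item{uwue_tau}{Quantile for the potential uWUE regression (0.95).}
#'   \item{uwue_min_days}{Minimum number of valid days required to fit the
#'     potential uWUE slope (60).}
#'   \item{molar_mass_c}{Molar mass of carbon, g mol-1 (12.011).}
#' }
#'
#' @return A list of class `"tl_config"`.
#' @export
#' @examples
#' cfg <- tl_config(clumping = 0.9)
#' cfg$clumping
tl_config <- function(...) {
  cfg <- list(
    par_sw_fraction = 0.45,
    solar_constant = 1361,
    albedo = 0.15,
    leaf_angle_deg = 60,
    clumping = 0.8,
    diffuse_coefs = c(0.9511, -0.1604, 4.388, -16.638, 12.336),
    diffuse_range = c(0.1, 1),
    theta_bar_deg = 57.5,
    beam_ratio_max = 10,
    k_beer = 0.5,
    vpd_open = 0.65,
    vpd_close = 2.5,
    t_min = -1,
    t_opt = 25,
    t_max = 40,
    gs_min = 0.001,
    gs_ref_max = 2,
    pm_invert_max_frac = 0.7,
    karman = 0.41,
    d_frac = 0.67,
    z0_frac = 0.1,
    ga_min = 0.001,
    pressure_kpa = 101.3,
    cp = 1.013e-3,
    sw_threshold = 5,
    qc_max = 1,
    sg_window = 15,
    sg_order = 2,
    season_smooth_days = 15,
    uwue_tau = 0.95,
    uwue_min_days = 60,
    molar_mass_c = 12.011
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad) || is.null(names(override)) || any(names(override) == "")) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(override)] <- override
  }
  if (cfg$sg_window %% 2 == 0) stop("sg_window must be odd")
  if (cfg$vpd_close <= cfg$vpd_open) stop("vpd_close must exceed vpd_open")
  if (!(cfg$t_min < cfg$t_opt && cfg$t_opt < cfg$t_max)) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max")
  }
  structure(cfg, class = "tl_config")
}
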