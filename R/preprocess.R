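# Preprocessing of half-hourly flux-tower data: daytime quality control,
# daily aggregation, uWUE transpiration partitioning, temperature-percentile
# season identification, and LAI/FPAR interpolation.

#' Daytime quality screening of half-hourly records
#'
#' Retains records whose shortwave irradiance strictly exceeds the daytime
#' threshold (default 5 W m-2) and, when a `qc` column is present, whose
#' quality flag does not exceed `config$qc_max` (measured or good gap-fill).
#' Record order is preserved; an empty result is allowed.
#'
#' @param records half-hourly data.frame with `sw_in` (W m-2) and optionally
#'   `qc`.
#' @param config a [tl_config()] list.
#' @return The retained subset of `records`.
#' @export
qc_filter_daytime <- function(records, config = tl_config()) {
  keep <- !is.na(records$sw_in) & records$sw_in > config$sw_threshold
  if (!is.null(records$qc)) {
    keep <- keep & (is.na(records$qc) | records$qc <= config$qc_max)
  }
  records[keep, , drop = FALSE]
}

#' Aggregate daytime half-hourly records to daily values
#'
#' Fluxes are integrated over the retained daytime records: GPP from
#' umol CO2 m-2 s-1 to gC m-2 d-1 via the molar mass of carbon, latent heat
#' to mm d-1 via the temperature-dependent latent heat of vaporization, and
#' available energy A = LE + H to MJ m-2 d-1. State variables (temperature,
#' RH, VPD, wind, CO2) are daytime means. Days with zero retained records
#' are omitted.
#'
#' @param records QC-filtered half-hourly data.frame with columns `date`,
#'   `ta`, `rh`, `vpd`, `ws`, `ca`, `gpp`, `le`, `h`, `sw_in`.
#' @param config a [tl_config()] list.
#' @param step_s timestep length, seconds (1800).
#' @return Daily data.frame with `date`, `doy`, `year`, daytime means,
#'   `par_mj`, `a_mj`, `gpp_obs` (gC m-2 d-1), `et_obs` (mm d-1),
#'   `daytime_s`.
#' @export
aggregate_daily <- function(records, config = tl_config(), step_s = 1800) {
  if (nrow(records) == 0) stop("no records to aggregate")
  f <- factor(records$date, levels = unique(records$date))
  agg_mean <- function(x) as.numeric(tapply(x, f, mean, na.rm = TRUE))
  agg_sum <- function(x) as.numeric(tapply(x, f, sum, na.rm = TRUE))
  ta_day <- agg_mean(records$ta)
  lambda <- psychrometrics(ta_day, config$pressure_kpa, config)$lambda
  n_rec <- as.numeric(table(f))
  out <- data.frame(
    date = as.Date(levels(f)),
    ta = ta_day,
    rh = agg_mean(records$rh),
    vpd = agg_mean(records$vpd),
    ws = agg_mean(records$ws),
    ca = agg_mean(records$ca),
    par_mj = agg_sum(par_from_shortwave(records$sw_in, config)) *
      step_s * 1e-6,
    a_mj = agg_sum(records$le + records$h) * step_s * 1e-6,
    gpp_obs = agg_sum(records$gpp) * config$molar_mass_c * 1e-6 * step_s,
    le_mj = agg_sum(records$le) * step_s * 1e-6,
    daytime_s = n_rec * step_s
  )
  # LE (MJ m-2 d-1) to water depth: 1 kg m-2 evaporated consumes lambda MJ.
  out$et_obs <- out$le_mj / lambda
  out$doy <- as.integer(format(out$date, "%j"))
  out$year <- as.integer(format(out$date, "%Y"))
  out
}

# Exact zero-intercept quantile regression slope: minimises the pinball loss
# sum(rho_tau(y - b x)) over b >= 0. The objective is piecewise linear and
# convex in b with breakpoints at the data ratios y_i/x_i, so the optimum is
# attained at one of them (internal).
quantile_slope_origin <- function(x, y, tau) {
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  cand <- sort(unique(pmax(y / x, 0)))
  loss <- vapply(cand, function(b) {
    r <- y - b * x
    sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
  }, numeric(1))
  cand[which.min(loss)]
}

#' Partition evapotranspiration into transpiration via uWUE
#'
#' The apparent underlying water-use efficiency of each day is
#' uWUE_a = GPP sqrt(VPD) / ET; the potential uWUE_p is the site-level slope
#' of a zero-intercept 95th-quantile regression of GPP sqrt(VPD) on ET.
#' Transpiration is Tc = ET * clamp(uWUE_a / uWUE_p, 0, 1), so the ratio of
#' transpiration to evapotranspiration is bounded by construction. Days with
#' ET <= 0 are flagged NA.
#'
#' @param daily data.frame with `gpp_obs` (gC m-2 d-1), `vpd` (kPa),
#'   `et_obs` (mm d-1).
#' @param config a [tl_config()] list (`uwue_tau`, `uwue_min_days`).
#' @return `daily` with added columns `uwue_a`, `tc_obs` and the attribute
#'   `uwue_p` (gC kPa^0.5 m-2 mm-1).
#' @export
partition_transpiration_uwue <- function(daily, config = tl_config()) {
  y <- daily$gpp_obs * sqrt(pmax(daily$vpd, 0))
  valid <- is.finite(y) & is.finite(daily$et_obs) & daily$et_obs > 0
  if (sum(valid) < config$uwue_min_days) {
    stop(sprintf("need at least %d valid days to fit uWUE_p (have %d)",
                 config$uwue_min_days, sum(valid)))
  }
  uwue_p <- quantile_slope_origin(daily$et_obs[valid], y[valid],
                                  config$uwue_tau)
  if (uwue_p <= 0) stop("degenerate potential uWUE (non-positive slope)")
  uwue_a <- ifelse(valid, y / daily$et_obs, NA_real_)
  ratio <- pmin(pmax(uwue_a / uwue_p, 0), 1)
  daily$uwue_a <- uwue_a
  daily$tc_obs <- ifelse(valid, daily$et_obs * ratio, NA_real_)
  attr(daily, "uwue_p") <- uwue_p
  daily
}

# Circular running mean over a day-of-year series (internal).
circular_running_mean <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  as.numeric(stats::filter(xx, rep(1 / window, window), sides = 2))[
    (half + 1):(half + n)]
}

#' Identify seasons from daytime temperature percentiles
#'
#' Computes the multi-year mean daytime temperature for each day of year,
#' smooths it with a circular running mean, and thresholds at the 25th and
#' 75th percentiles of all valid daily daytime means: winter is below the
#' 25th percentile, summer is the longest contiguous block above the 75th,
#' and spring/autumn are the warming/cooling transitions between them. The
#' returned windows are contiguous (spring end + 1 = summer start, etc.).
#'
#' @param daily data.frame with `doy` and daytime-mean temperature `ta`.
#' @param config a [tl_config()] list (`season_smooth_days`).
#' @return List of class `"tl_seasons"` with elements `spring`, `summer`,
#'   `autumn` (each `c(doy_start, doy_end)`) and the thresholds `p25`, `p75`.
#' @export
identify_seasons <- function(daily, config = tl_config()) {
  ok <- is.finite(daily$ta) & is.finite(daily$doy)
  doy <- daily$doy[ok]
  ta <- daily$ta[ok]
  mean_doy <- rep(NA_real_, 365)
  m <- tapply(ta, pmin(doy, 365), mean)
  mean_doy[as.integer(names(m))] <- as.numeric(m)
  if (anyNA(mean_doy)) {
    mean_doy <- stats::approx(which(!is.na(mean_doy)),
                              mean_doy[!is.na(mean_doy)],
                              xout = seq_len(365), rule = 2)$y
  }
  sm <- circular_running_mean(mean_doy, config$season_smooth_days)
  p <- stats::quantile(ta, c(0.25, 0.75), names = FALSE)
  if (max(sm) <= p[2] || min(sm) >= p[1] || max(sm) <= p[1] || min(sm) >= p[2]) {
    stop("no seasonal cycle: smoothed temperature never crosses a threshold")
  }
  above <- sm > p[2]
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hot <- which(runs$values)
  i <- hot[which.max(runs$lengths[hot])]
  summer <- c(starts[i], ends[i])
  below_before <- which(sm[seq_len(summer[1])] < p[1])
  below_after <- which(sm[summer[2]:365] < p[1]) + summer[2] - 1
  if (!length(below_before) || !length(below_after)) {
    stop("no seasonal cycle: transitions do not reach the winter threshold")
  }
  spring <- c(max(below_before) + 1, summer[1] - 1)
  autumn <- c(summer[2] + 1, min(below_after) - 1)
  if (spring[1] > spring[2] || autumn[1] > autumn[2]) {
    stop("degenerate transition seasons")
  }
  structure(list(spring = spring, summer = summer, autumn = autumn,
                 p25 = p[1], p75 = p[2]),
            class = "tl_seasons")
}

#' @export
print.tl_seasons <- function(x, ...) {
  cat(sprintf("<tl_seasons> spring %d-%d  summer %d-%d  autumn %d-%d\n",
              x$spring[1], x$spring[2], x$summer[1], x$summer[2],
              x$autumn[1], x$autumn[2]))
  invisible(x)
}

#' Assign a season label to days of year
#'
#' @param doy integer day-of-year vector.
#' @param seasons a [identify_seasons()] result.
#' @return Character vector: `"spring"`, `"summer"`, `"autumn"` or NA for
#'   winter days outside the growing season.
#' @export
season_of_doy <- function(doy, seasons) {
  out <- rep(NA_character_, length(doy))
  for (s in c("spring", "summer", "autumn")) {
    w <- seasons[[s]]
    out[doy >= w[1] & doy <= w[2]] <- s
  }
  out
}

#' Interpolate 8-day LAI/FPAR composites to daily series
#'
#' Linear interpolation to daily resolution followed by Savitzky-Golay
#' smoothing, with the result clipped to physical ranges (LAI >= 0,
#' FPAR in \[0, 1\]).
#'
#' @param series data.frame with columns `t` (composite time, days,
#'   strictly increasing), `lai`, `fpar`.
#' @param t_out daily output times (default each day spanned by `series`).
#' @param config a [tl_config()] list (`sg_window`, `sg_order`).
#' @return data.frame with `t`, `lai`, `fpar` at daily resolution.
#' @export
interpolate_lai_fpar <- function(series, t_out = NULL,
                                 config = tl_config()) {
  if (nrow(series) < 2) stop("need at least two composite points")
  if (any(diff(series$t) <= 0)) stop("composite times must be increasing")
  if (is.null(t_out)) t_out <- seq(min(series$t), max(series$t))
  smooth_one <- function(v, lo, hi) {
    daily <- stats::approx(series$t, v, xout = t_out, rule = 2)$y
    if (length(daily) >= config$sg_window) {
      daily <- signal::sgolayfilt(daily, p = config$sg_order,
                                  n = config$sg_window)
    }
    pmin(hi, pmax(lo, daily))
  }
  data.frame(t = t_out,
             lai = smooth_one(series$lai, 0, Inf),
             fpar = smooth_one(series$fpar, 0, 1))
}
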