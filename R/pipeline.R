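#' Run the end-to-end synthetic experiment
#'
#' Orchestrates the whole chain on a synthetic site: generates half-hourly
#' drivers and LAI/FPAR composites, forward-simulates daily fluxes with the
#' site's true seasonal parameters, prepares the calibration dataset
#' (Penman-Monteith inputs and reference conductance) and runs the paired
#' randomized calibration/validation experiments for both parameterization
#' schemes.
#'
#' @param spec a [synthetic_site()] specification.
#' @param config a [tl_config()] list.
#' @param calib calibration settings (see [calibrate_scheme()]).
#' @param n_experiments number of randomized 70/30 splits.
#' @param seed master seed for the experiment splits and optimizer streams.
#' @return List with `daily` (forward-simulated dataset with `gs_ref`),
#'   `pm`, `seasons`, `experiments` ([run_randomized_experiments()] result)
#'   and `comparison` ([compare_schemes()] table).
#' @export
run_tl_pipeline <- function(spec = synthetic_site(), config = tl_config(),
                            calib = list(), n_experiments = 50, seed = 1) {
  meteo <- generate_meteo(spec, config)
  lai <- generate_lai_fpar(spec, config)
  daily <- forward_simulate(spec, meteo, lai, config)
  prep <- prepare_calibration_data(daily, spec$measurement_height,
                                   spec$canopy_height, config)
  experiments <- run_randomized_experiments(prep$data, prep$pm, config,
                                            calib, n_experiments,
                                            seed = seed)
  list(daily = prep$data, pm = prep$pm,
       seasons = attr(daily, "seasons"),
       experiments = experiments,
       comparison = compare_schemes(experiments))
}
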