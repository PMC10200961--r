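#' Physiological parameter set
#'
#' The four calibrated parameters of the model chain: maximum light use
#' efficiencies of sunlit and shaded leaves (`eps_msu`, `eps_msh`, gC MJ-1)
#' and the Ball-Berry slopes for sunlit and shaded leaves (`g_su`, `g_sh`,
#' dimensionless), tagged with the season they apply to.
#'
#' Bounds are the published calibration ranges for temperate deciduous
#' forests: eps_msu in \[0.34, 1.50\] and eps_msh in \[2.71, 4.79\] gC MJ-1;
#' both Ball-Berry slopes in \[0, 60\].
#'
#' @param eps_msu maximum LUE of sunlit leaves, gC MJ-1.
#' @param eps_msh maximum LUE of shaded leaves, gC MJ-1.
#' @param g_su Ball-Berry slope, sunlit leaves.
#' @param g_sh Ball-Berry slope, shaded leaves.
#' @param season one of `"spring"`, `"summer"`, `"autumn"`, `"all"`.
#' @return An object of class `"tl_params"` (a named list).
#' @export
#' @examples
#' parameter_set(0.75, 3.05, 10, 8, "summer")
parameter_set <- function(eps_msu, eps_msh, g_su, g_sh, season = "all") {
  season <- match.arg(season, c("spring", "summer", "autumn", "all"))
  b <- param_bounds()
  vals <- c(eps_msu = eps_msu, eps_msh = eps_msh, g_su = g_su, g_sh = g_sh)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.finite(v) || v < b[nm, "lower"] || v > b[nm, "upper"]) {
      stop(sprintf("%s = %g outside calibration bounds [%g, %g]",
                   nm, v, b[nm, "lower"], b[nm, "upper"]))
    }
  }
  structure(list(eps_msu = eps_msu, eps_msh = eps_msh,
                 g_su = g_su, g_sh = g_sh, season = season),
            class = "tl_params")
}

#' Calibration bounds of the four physiological parameters
#'
#' @return A 4x2 matrix with rows `eps_msu`, `eps_msh`, `g_su`, `g_sh` and
#'   columns `lower`, `upper`.
#' @export
param_bounds <- function() {
  matrix(c(0.34, 1.50,
           2.71, 4.79,
           0, 60,
           0, 60),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("eps_msu", "eps_msh", "g_su", "g_sh"),
                         c("lower", "upper")))
}

#' @export
print.tl_params <- function(x, ...) {
  cat(sprintf(
    "<tl_params %s> eps_msu=%.3g eps_msh=%.3g gC/MJ; g_su=%.3g g_sh=%.3g\n",
    x$season, x$eps_msu, x$eps_msh, x$g_su, x$g_sh))
  invisible(x)
}
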