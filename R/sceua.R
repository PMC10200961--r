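# Shuffled Complex Evolution (SCE-UA) global optimizer, following the
# Duan, Sorooshian & Gupta formulation: a population of points in a bounded
# box is partitioned into complexes, each complex evolves by competitive
# simplex (reflection / contraction / mutation) steps on triangularly
# sampled subcomplexes, and complexes are periodically shuffled.

#' SCE-UA bounded global minimization
#'
#' @param fn objective function of a numeric parameter vector; must be
#'   evaluable everywhere in the box (non-finite values are treated as
#'   +Inf, but an initial population that is more than half non-finite
#'   aborts).
#' @param lower,upper numeric bound vectors of equal length (finite).
#' @param control list of algorithm settings, merged over defaults:
#'   `ngs` complexes (4), `npg` points per complex (2n+1), `nps` subcomplex
#'   size (n+1), `nspl` evolution steps per complex per shuffle (npg),
#'   `maxn` maximum function evaluations (5000), `kstop` shuffles over which
#'   improvement is measured (10), `pcento` minimum relative improvement
#'   over `kstop` shuffles (1e-5), `peps` normalized parameter-range
#'   convergence (1e-5).
#' @param seed integer seed; the run is deterministic given the seed and
#'   global RNG state is restored afterwards.
#' @return List with `par` (argmin), `value`, `counts` (function
#'   evaluations), `trace` (best objective after each shuffle),
#'   `convergence` (`"pcento"`, `"peps"` or `"maxn"`).
#' @export
#' @examples
#' sceua_minimize(function(x) sum((x - c(1, 2))^2),
#'                lower = c(-5, -5), upper = c(5, 5), seed = 1)$par
sceua_minimize <- function(fn, lower, upper, control = list(), seed = 1) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  ctrl <- list(ngs = 4, npg = 2 * n + 1, nps = n + 1, nspl = NULL,
               maxn = 5000, kstop = 10, pcento = 1e-5, peps = 1e-5)
  ctrl[names(control)] <- control
  if (is.null(ctrl$nspl)) ctrl$nspl <- ctrl$npg
  rng <- upper - lower
  safe_fn <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) Inf else v
  }
  with_seed(seed, {
    npt <- ctrl$ngs * ctrl$npg
    pop <- matrix(stats::runif(npt * n), ncol = n)
    pop <- sweep(sweep(pop, 2, rng, "*"), 2, lower, "+")
    fv <- apply(pop, 1, safe_fn)
    if (mean(!is.finite(fv)) > 0.5) {
      stop("objective non-finite on more than half of the initial points")
    }
    neval <- npt
    ord <- order(fv)
    pop <- pop[ord, , drop = FALSE]
    fv <- fv[ord]
    trace <- numeric(0)
    best_hist <- fv[1]
    convergence <- "maxn"
    # triangular selection probabilities over a sorted complex
    sel_prob <- 2 * (ctrl$npg + 1 - seq_len(ctrl$npg)) /
      (ctrl$npg * (ctrl$npg + 1))
    repeat {
      for (igs in seq_len(ctrl$ngs)) {
        cx_idx <- seq(igs, npt, by = ctrl$ngs)
        cx <- pop[cx_idx, , drop = FALSE]
        cf <- fv[cx_idx]
        for (loop in seq_len(ctrl$nspl)) {
          lcs <- sort(sample.int(ctrl$npg, ctrl$nps, prob = sel_prob))
          sx <- cx[lcs, , drop = FALSE]
          sf <- cf[lcs]
          worst <- which.max(sf)
          centroid <- colMeans(sx[-worst, , drop = FALSE])
          newp <- 2 * centroid - sx[worst, ]
          if (any(newp < lower | newp > upper)) {
            newp <- lower + stats::runif(n) * rng
          }
          newf <- safe_fn(newp)
          neval <- neval + 1
          if (newf >= sf[worst]) {
            newp <- (centroid + sx[worst, ]) / 2
            newf <- safe_fn(newp)
            neval <- neval + 1
            if (newf >= sf[worst]) {
              newp <- lower + stats::runif(n) * rng
              newf <- safe_fn(newp)
              neval <- neval + 1
            }
          }
          cx[lcs[worst], ] <- newp
          cf[lcs[worst]] <- newf
          cord <- order(cf)
          cx <- cx[cord, , drop = FALSE]
          cf <- cf[cord]
        }
        pop[cx_idx, ] <- cx
        fv[cx_idx] <- cf
      }
      ord <- order(fv)
      pop <- pop[ord, , drop = FALSE]
      fv <- fv[ord]
      trace <- c(trace, fv[1])
      best_hist <- c(best_hist, fv[1])
      if (length(best_hist) > ctrl$kstop + 1) {
        improve <- best_hist[length(best_hist) - ctrl$kstop] - fv[1]
        if (improve <= ctrl$pcento * max(abs(fv[1]), 1e-12)) {
          convergence <- "pcento"
          break
        }
      }
      span <- exp(mean(log(pmax(
        apply(pop, 2, max) - apply(pop, 2, min), 1e-300) / rng)))
      if (span < ctrl$peps) {
        convergence <- "peps"
        break
      }
      if (neval >= ctrl$maxn) break
    }
    list(par = pop[1, ], value = fv[1], counts = neval, trace = trace,
         convergence = convergence)
  })
}
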