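# Model-evaluation statistics: Willmott's agreement index, RMSE, Pearson
# correlation and a least-squares AIC.

#' Willmott's index of agreement
#'
#' d = 1 - sum((P - O)^2) / sum((|P - Obar| + |O - Obar|)^2) with Obar the
#' observed mean; bounded in \[0, 1\], 1 for perfect agreement, and
#' invariant to a common additive shift of predictions and observations.
#'
#' @param predicted,observed equal-length numeric vectors (n >= 2); pairs
#'   with missing values are dropped.
#' @return d in \[0, 1\].
#' @export
#' @examples
#' agreement_index(c(2, 0), c(0, 2)) # antisymmetric two-point case: 0
agreement_index <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ok <- is.finite(predicted) & is.finite(observed)
  p <- predicted[ok]
  o <- observed[ok]
  if (length(o) < 2) stop("need at least two paired values")
  if (max(o) == min(o)) stop("degenerate observed series: no variability")
  obar <- mean(o)
  den <- sum((abs(p - obar) + abs(o - obar))^2)
  if (den == 0) stop("degenerate observed series: no variability")
  max(0, min(1, 1 - sum((p - o)^2) / den))
}

#' Evaluation metric set
#'
#' RMSE, Pearson correlation, Willmott's d and a least-squares AIC
#' (n log(SSE/n) + 2k, SSE floored at 1e-12) for a predicted/observed pair.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @param k number of calibrated parameters charged to the model.
#' @return One-row data.frame with `aic`, `rmse`, `r`, `d`, `n`.
#' @export
flux_metrics <- function(predicted, observed, k) {
  ok <- is.finite(predicted) & is.finite(observed)
  p <- predicted[ok]
  o <- observed[ok]
  n <- length(o)
  if (n <= k + 1) stop("too few paired values for the metric set")
  sse <- max(sum((p - o)^2), 1e-12)
  data.frame(
    aic = n * log(sse / n) + 2 * k,
    rmse = sqrt(sse / n),
    r = if (stats::sd(p) > 0 && stats::sd(o) > 0) stats::cor(p, o) else NA_real_,
    d = agreement_index(p, o),
    n = n
  )
}
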