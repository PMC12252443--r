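#' Root-mean-square error
#'
#' RMSE = sqrt(mean((y - yhat)^2)).  Multi-attribute inputs (matrices or
#' arrays) are flattened, so the RMSE of a multivariate forecast window is the
#' RMSE over all its residuals.
#'
#' @param actual Observed values (vector, matrix or array).
#' @param predicted Predicted values, same shape as `actual`.
#' @return Non-negative scalar; 0 iff the two inputs are identical.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25/2)
rmse <- function(actual, predicted) {
  a <- as.numeric(actual)
  p <- as.numeric(predicted)
  if (length(a) != length(p)) stop("actual and predicted lengths differ")
  if (length(a) < 1) stop("need at least one observation")
  sqrt(mean((a - p)^2))
}

#' Coefficient of determination
#'
#' R^2 = 1 - RSS/TSS.  Equals 1 for a perfect prediction, 0 for the
#' mean predictor, and can be negative when the prediction is worse than the
#' mean predictor.
#'
#' @inheritParams rmse
#' @return Scalar <= 1.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(3, 2, 1))  # -3
r_squared <- function(actual, predicted) {
  a <- as.numeric(actual)
  p <- as.numeric(predicted)
  if (length(a) != length(p)) stop("actual and predicted lengths differ")
  if (length(a) < 2) stop("need at least two observations")
  tss <- sum((a - mean(a))^2)
  if (tss == 0) stop("actual values are constant; R^2 undefined (TSS = 0)")
  1 - sum((a - p)^2) / tss
}

#' Relative reduction of a loss versus a baseline
#'
#' Percent by which `value` undercuts `baseline`:
#' 100 x (baseline - value) / baseline.  Used to compare a model's loss
#' against literature baselines (e.g. a 0.16 loss versus a 0.3 baseline is a
#' 46.67% reduction).
#'
#' @param baseline Baseline (reference) loss, > 0.
#' @param value Achieved loss.
#' @return Percent reduction (positive when `value < baseline`).
#' @export
relative_reduction <- function(baseline, value) {
  stopifnot(is.numeric(baseline), is.numeric(value))
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * (baseline - value) / baseline
}
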