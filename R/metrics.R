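# Evaluation metrics comparing forecast trait values against actual ones,
# plus single-class mAP50 for detector quality.

check_series <- function(actual, forecast) {
  if (length(actual) != length(forecast)) stopf("actual and forecast must have equal length")
  if (length(actual) < 1L) stopf("empty series")
  invisible(NULL)
}

#' Mean absolute percentage error
#'
#' `MAPE = 100/n * sum(|actual - forecast| / actual)`, in percent.
#'
#' @param actual,forecast Numeric vectors of equal length; `actual` must
#'   be nonzero.
#' @return Percent value.
#' @export
mape <- function(actual, forecast) {
  check_series(actual, forecast)
  if (any(actual == 0)) stopf("MAPE undefined: actual contains zero")
  mean(abs(actual - forecast) / abs(actual)) * 100
}

#' Root mean square error
#' @inheritParams mape
#' @return Value in the units of the inputs.
#' @export
rmse <- function(actual, forecast) {
  check_series(actual, forecast)
  sqrt(mean((actual - forecast)^2))
}

#' Mean absolute error
#' @inheritParams mape
#' @return Value in the units of the inputs.
#' @export
mae <- function(actual, forecast) {
  check_series(actual, forecast)
  mean(abs(actual - forecast))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((actual - forecast)^2) / sum((actual - mean(actual))^2)`.
#' The centering mean is taken over the actual values.
#'
#' @inheritParams mape
#' @return Dimensionless value `<= 1` (negative when the forecast is worse
#'   than the mean of the actual values).
#' @export
r_squared <- function(actual, forecast) {
  check_series(actual, forecast)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stopf("R^2 undefined: actual values have zero variance")
  1 - sum((actual - forecast)^2) / ss_tot
}

#' Counting/measurement accuracy
#'
#' `accuracy = (1 - MAE / mean(actual)) * 100`, in percent. The
#' denominator is the mean of the actual values (an MAE-to-single-value
#' ratio is undefined for a series).
#'
#' @inheritParams mape
#' @return Percent value.
#' @seealso [accuracy_mape_complement()] for the per-item alternative.
#' @export
accuracy <- function(actual, forecast) {
  check_series(actual, forecast)
  if (any(actual == 0)) stopf("accuracy undefined: actual contains zero")
  (1 - mae(actual, forecast) / mean(actual)) * 100
}

#' Per-item accuracy complement of MAPE
#'
#' The alternative reading of the accuracy formula with a per-item
#' denominator: `mean(1 - |actual - forecast| / actual) * 100`, which
#' equals `100 - MAPE`.
#'
#' @inheritParams mape
#' @return Percent value.
#' @export
accuracy_mape_complement <- function(actual, forecast) {
  100 - mape(actual, forecast)
}

#' Full metric report for a paired series
#'
#' @inheritParams mape
#' @return One-row tibble: `n`, `mae`, `rmse`, `mape_percent`, `r2`,
#'   `accuracy_percent`, `accuracy_mape_complement`.
#' @export
metric_report <- function(actual, forecast) {
  check_series(actual, forecast)
  tibble::tibble(
    n = length(actual),
    mae = mae(actual, forecast),
    rmse = rmse(actual, forecast),
    mape_percent = mape(actual, forecast),
    r2 = r_squared(actual, forecast),
    accuracy_percent = accuracy(actual, forecast),
    accuracy_mape_complement = accuracy_mape_complement(actual, forecast)
  )
}

#' Single-class mean average precision at IoU 0.5
#'
#' PASCAL-style AP with continuous (all-points) interpolation:
#' predictions are visited in order of decreasing confidence and matched
#' greedily to the not-yet-matched ground-truth box of highest IoU within
#' the same image, a match requiring IoU >= 0.5; the AP is the area under
#' the interpolated precision–recall curve.
#'
#' @param pred Detection tibble of predictions (with confidences).
#' @param truth Detection tibble of ground-truth boxes.
#' @param iou_threshold Match threshold (default 0.5).
#' @return AP value in `[0, 1]`.
#' @export
map50 <- function(pred, truth, iou_threshold = 0.5) {
  if (nrow(truth) == 0L) stopf("mAP undefined: empty ground truth")
  n_truth <- nrow(truth)
  if (nrow(pred) == 0L) return(0)
  ord <- order(-pred$confidence, pred$x_min, pred$y_min)
  pred <- pred[ord, , drop = FALSE]
  matched <- rep(FALSE, n_truth)
  tp <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    same <- which(truth$image_id == pred$image_id[i] & !matched)
    if (length(same)) {
      ious <- box_iou(pred[rep(i, length(same)), , drop = FALSE],
                      truth[same, , drop = FALSE])
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        matched[same[j]] <- TRUE
        tp[i] <- 1
      }
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_truth
  # all-points interpolation: precision envelope from the right
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}
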