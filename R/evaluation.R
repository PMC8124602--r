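# Evaluation metrics: per-target RMSE, MAE, MRE, R^2, aggregate total MSE
# and mean estimation time.

check_pair <- function(measured, estimated) {
  if (length(measured) == 0) stop("empty input")
  if (length(measured) != length(estimated)) stop("length mismatch")
  if (any(!is.finite(measured)) || any(!is.finite(estimated)))
    stop("non-finite values")
  invisible(TRUE)
}

#' Root mean square error
#' @param measured,estimated numeric vectors of equal, non-zero length.
#' @return a single number.
#' @export
rmse <- function(measured, estimated) {
  check_pair(measured, estimated)
  sqrt(mean((measured - estimated)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return a single number.
#' @export
mae <- function(measured, estimated) {
  check_pair(measured, estimated)
  mean(abs(measured - estimated))
}

#' Mean relative error (percent)
#'
#' Mean of `|measured - estimated| / measured`, in percent; the denominator
#' is the measured (ground-truth) value.
#'
#' @inheritParams rmse
#' @return a single number (percent).
#' @export
mre <- function(measured, estimated) {
  check_pair(measured, estimated)
  if (any(measured == 0)) stop("measured values must be non-zero for MRE")
  mean(abs(measured - estimated) / measured) * 100
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the mean of
#' the measured values.
#'
#' @inheritParams rmse
#' @return a single number (at most 1; negative when the estimates are
#'   worse than the measured mean).
#' @export
r_squared <- function(measured, estimated) {
  check_pair(measured, estimated)
  if (length(measured) < 2) stop("need at least 2 samples")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("measured values are constant; R^2 undefined")
  1 - sum((measured - estimated)^2) / ss_tot
}

#' Evaluate a model on a dataset
#'
#' Runs the model over every sample and reports per-target RMSE, MAE, MRE
#' and R^2, plus the aggregate total MSE (sum over targets of the squared
#' RMSEs, mixed kg^2/cm^2 units) and the mean wall-clock estimation time
#' per image (hardware-dependent; report-only).
#'
#' @param model a `pig_regressor` with initialised weights.
#' @param dataset a `regression_dataset` at the model input size.
#' @param batch_size forward-pass batch size.
#' @return an object of class `metrics_report`: `per_target` (data frame
#'   with one row per target), `total_mse`, `mean_estimation_time_ms`, `n`.
#' @export
evaluate <- function(model, dataset, batch_size = 32L) {
  stopifnot(inherits(model, "pig_regressor"), inherits(dataset, "regression_dataset"))
  n <- dim(dataset$images)[3]
  t0 <- Sys.time()
  pred <- predict(model, dataset$images, batch_size = batch_size)
  elapsed_ms <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  per_target <- data.frame(
    target = TARGET_NAMES,
    unit = c("kg", "cm", "cm", "cm", "cm", "cm"),
    rmse = vapply(1:6, function(j) rmse(dataset$labels[, j], pred[, j]), 0),
    mae = vapply(1:6, function(j) mae(dataset$labels[, j], pred[, j]), 0),
    mre = vapply(1:6, function(j) mre(dataset$labels[, j], pred[, j]), 0),
    r_squared = vapply(1:6, function(j) r_squared(dataset$labels[, j], pred[, j]), 0),
    stringsAsFactors = FALSE)
  structure(list(per_target = per_target,
                 total_mse = sum(per_target$rmse^2),
                 mean_estimation_time_ms = elapsed_ms / n,
                 n = n, predictions = pred),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  df <- x$per_target
  df$rmse <- sprintf("%.3f", df$rmse)
  df$mae <- sprintf("%.3f", df$mae)
  df$mre <- sprintf("%.2f%%", df$mre)
  df$r_squared <- sprintf("%.4f", df$r_squared)
  print(df, row.names = FALSE)
  cat(sprintf("total MSE (kg^2): %.3f   mean estimation time: %.2f ms/image\n",
              x$total_mse, x$mean_estimation_time_ms))
  invisible(x)
}
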