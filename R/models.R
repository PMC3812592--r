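#' Cross-validation accuracy statistics
#'
#' \eqn{RMSE = \sqrt{\sum (y - \hat y)^2 / n}},
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2} (one minus
#' PRESS over total sum of squares, so a biased predictor can score below
#' zero), and \eqn{\%RMSE = 100\, RMSE / center(y)} with the mean (default)
#' or median of the response as denominator.
#'
#' @param y Observed response.
#' @param yhat Predictions (same length, n >= 2).
#' @param center \code{"mean"} or \code{"median"}.
#' @return List with \code{R2}, \code{RMSE}, \code{pct_RMSE}.
#' @export
accuracy_stats <- function(y, yhat, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 2L) stop("need at least 2 observations")
  sstot <- sum((y - mean(y))^2)
  if (sstot < 1e-24) stop("zero variance in y")
  press <- sum((y - yhat)^2)
  rmse <- sqrt(press / length(y))
  ctr <- if (center == "mean") mean(y) else stats::median(y)
  list(R2 = 1 - press / sstot, RMSE = rmse, pct_RMSE = 100 * rmse / ctr)
}

#' Bundle out-of-fold predictions into a cross-validation result
#'
#' Also records the calibration RMSE when supplied and flags (as a warning
#' condition stored on the object, not an error) calibration/CV RMSE
#' disagreement beyond 2 percent, the paper-style overfitting check.
#'
#' @param y Observed response.
#' @param predictions Out-of-fold predictions.
#' @param complexity Model complexity (number of PLS factors, or SVR cost C).
#' @param center Percent-RMSE denominator statistic.
#' @param cal_rmse Optional calibration (training) RMSE.
#' @return Object of class \code{"cv_result"}.
#' @export
cv_result <- function(y, predictions, complexity = NA_real_,
                      center = c("mean", "median"), cal_rmse = NA_real_) {
  center <- match.arg(center)
  st <- accuracy_stats(y, predictions, center)
  structure(list(predictions = predictions, y = y,
                 R2 = st$R2, RMSE = st$RMSE, pct_RMSE = st$pct_RMSE,
                 complexity = complexity, cal_RMSE = cal_rmse,
                 overfit_flag = is.finite(cal_rmse) && st$RMSE > 0 &&
                   abs(cal_rmse - st$RMSE) / st$RMSE > 0.02),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: R2=%.3f RMSE=%.4f %%RMSE=%.2f complexity=%s>\n",
              x$R2, x$RMSE, x$pct_RMSE, format(x$complexity)))
  invisible(x)
}

#' Leave-one-out cross-validation of an arbitrary fitter
#'
#' For each sample the fitter is applied to the other \code{n - 1} samples
#' and the held-out sample is predicted.  All data-dependent quantities
#' (centering, scaling, scatter-correction references) must live inside
#' \code{fitter} so that nothing leaks across folds.  The result does not
#' depend on sample order.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param fitter \code{function(X_train, y_train)} returning an object with a
#'   \code{predict(object, newdata)} method.
#' @param center Percent-RMSE denominator statistic.
#' @param complexity Complexity value to record on the result.
#' @return A \code{\link{cv_result}}.
#' @export
loocv <- function(X, y, fitter, center = c("mean", "median"),
                  complexity = NA_real_) {
  center <- match.arg(center)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out CV needs at least 3 samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fitter(X[-i, , drop = FALSE], y[-i]),
                    error = function(e)
                      stop("fold ", i, " failed: ", conditionMessage(e)))
    preds[i] <- stats::predict(fit, X[i, , drop = FALSE])
  }
  full <- fitter(X, y)
  cal_rmse <- sqrt(mean((stats::predict(full, X) - y)^2))
  cv_result(y, preds, complexity = complexity, center = center,
            cal_rmse = cal_rmse)
}

#' Ordinary least squares regression
#'
#' Least-squares fit with intercept; requires more samples than coefficients
#' and a full-rank design.
#'
#' @param X Predictor matrix (n x p, n >= p + 1; equality gives an exactly
#'   determined fit, as happens in the smallest leave-one-out folds).
#' @param y Response vector.
#' @return Object of class \code{"olsr_model"}.
#' @export
fit_olsr <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L) stop("OLSR needs n >= p + 1 samples")
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient design in OLSR")
  cf <- qr.coef(qrD, y)
  structure(list(intercept = cf[1L], coefficients = cf[-1L],
                 residuals = y - drop(D %*% cf)),
            class = "olsr_model")
}

#' @export
predict.olsr_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' @export
print.olsr_model <- function(x, ...) {
  cat(sprintf("<olsr_model: %d coefficient(s) + intercept>\n",
              length(x$coefficients)))
  invisible(x)
}
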