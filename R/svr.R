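minmax_params <- function(X) {
  rows <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  lo <- do.call(pmin, rows)
  hi <- do.call(pmax, rows)
  rng <- hi - lo
  rng[rng < 1e-15] <- 1        # constant features map to 0
  list(lo = lo, rng = rng)
}

minmax_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$lo), 2L, sc$rng, "/")
}

#' Fit a linear epsilon-insensitive support vector regression
#'
#' Features are min-max scaled to \code{[0, 1]} (scaling derived from the
#' training data handed in, so cross-validation folds each derive their own),
#' and the linear-kernel dual is solved by exact coordinate descent.  The
#' intercept is absorbed into the kernel as a constant feature
#' (regularised-bias formulation), which removes the equality constraint and
#' gives each coordinate a closed-form soft-threshold update.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param C Cost parameter (> 0): weight of tube violations against model
#'   flatness.
#' @param epsilon Half-width of the insensitive tube (default 0.1): residuals
#'   smaller than \code{epsilon} incur no loss.
#' @param max_iter,tol Coordinate-descent iteration cap and convergence
#'   tolerance on the largest dual-coefficient change.
#' @return Object of class \code{"svr_model"} with the weight vector on the
#'   scaled features, the intercept, the scaling parameters and the number of
#'   support vectors.
#' @export
fit_svr_single <- function(X, y, C, epsilon = 0.1,
                           max_iter = 20000L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (C <= 0) stop("C must be positive")
  n <- nrow(X)
  if (n < 3L) stop("SVR needs at least 3 samples")
  sc <- minmax_params(X)
  Xs <- minmax_apply(X, sc)
  K <- tcrossprod(Xs) + 1          # +1 = regularised bias term
  beta <- svr_dual_cd(K, y, C, epsilon, as.integer(max_iter), tol,
                      numeric(n))
  structure(list(w = drop(crossprod(Xs, beta)), b = sum(beta),
                 beta = beta, C = C, epsilon = epsilon, scaling = sc,
                 n_support = sum(abs(beta) > 1e-12)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  Xs <- minmax_apply(as.matrix(newdata), object$scaling)
  drop(Xs %*% object$w) + object$b
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model: C=%g eps=%g, %d support vector(s)>\n",
              x$C, x$epsilon, x$n_support))
  invisible(x)
}

#' Default cost grid for the SVR search
#'
#' @return Logarithmic grid \code{2^-10 .. 2^3}.
#' @export
default_C_grid <- function() 2^seq(-10, 3)

#' Grid-searched linear SVR under leave-one-out cross-validation
#'
#' Every cost value in the grid is evaluated by leave-one-out
#' cross-validation (feature scaling re-derived inside each fold); the
#' selected cost is the \emph{smallest} one whose CV RMSE lies within 2
#' percent of the grid minimum, mirroring the parsimony rule used for the
#' PLS factor count.  \code{epsilon} stays fixed at 0.1.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param C_grid Positive cost grid (default \code{\link{default_C_grid}}).
#' @param epsilon Tube half-width.
#' @param center Percent-RMSE denominator statistic.
#' @return List with the refitted \code{model} (class \code{"svr_model"}),
#'   the \code{cv} result at the chosen cost, the chosen \code{C} and the
#'   full \code{rmse_grid}.
#' @export
fit_svr <- function(X, y, C_grid = default_C_grid(), epsilon = 0.1,
                    center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(C_grid) == 0L) stop("empty C grid")
  if (any(C_grid <= 0)) stop("C grid must be positive")
  C_grid <- sort(C_grid)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out CV needs at least 3 samples")
  # per fold: scale once, build the kernel once, warm-start across the grid
  preds <- matrix(NA_real_, n, length(C_grid))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    sc <- minmax_params(Xtr)
    Xs <- minmax_apply(Xtr, sc)
    K <- tcrossprod(Xs) + 1
    kte <- drop(Xs %*% drop(minmax_apply(X[i, , drop = FALSE], sc))) + 1
    beta <- numeric(n - 1L)
    for (ci in seq_along(C_grid)) {
      beta <- svr_dual_cd(K, y[-i], C_grid[ci], epsilon, 20000L, 1e-10, beta)
      preds[i, ci] <- sum(beta * kte)
    }
  }
  rmse <- sqrt(colMeans((preds - y)^2))
  chosen <- which(rmse <= 1.02 * min(rmse))[1L]
  model <- fit_svr_single(X, y, C = C_grid[chosen], epsilon = epsilon)
  cal_rmse <- sqrt(mean((predict(model, X) - y)^2))
  cv <- cv_result(y, preds[, chosen], complexity = C_grid[chosen],
                  center = center, cal_rmse = cal_rmse)
  list(model = model, cv = cv, C = C_grid[chosen],
       rmse_grid = stats::setNames(rmse, format(C_grid)))
}
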