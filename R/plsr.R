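#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression with a single response, computed by the
#' NIPALS algorithm on the mean-centred predictor matrix and response (no
#' variance scaling).  Latent factors are extracted sequentially; scores are
#' mutually orthogonal, and at full rank the training predictions coincide
#' with ordinary least squares.
#'
#' @param X Numeric matrix, samples x predictors.
#' @param y Numeric response vector.
#' @param nfactors Number of latent factors to extract (capped at the rank of
#'   the centred \code{X}; an error is raised if the request exceeds
#'   \code{min(n - 1, p)}).
#' @return Object of class \code{"plsr_model"} with weights \code{W},
#'   loadings \code{P}, response loadings \code{q}, scores \code{TT},
#'   centering vectors, and per-factor coefficient access through
#'   \code{\link{plsr_coefficients}}.
#' @export
fit_plsr <- function(X, y, nfactors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("PLSR needs at least 3 samples")
  if (length(y) != n) stop("length of y must match rows of X")
  if (stats::sd(y) < 1e-15) stop("zero-variance response")
  if (nfactors < 1L || nfactors > min(n - 1L, p))
    stop("nfactors must lie in [1, min(n-1, p)]")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2L, x_center)
  f <- y - y_center
  ssx0 <- sum(E * E)
  W <- matrix(0, p, nfactors); P <- matrix(0, p, nfactors)
  TT <- matrix(0, n, nfactors); q <- numeric(nfactors)
  A <- 0L
  for (a in seq_len(nfactors)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12 * (1 + ssx0)) break      # X residual exhausted
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t * t)
    if (tt < 1e-24) break
    pvec <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; q[a] <- qa
    A <- a
  }
  if (A == 0L) stop("no PLS factor could be extracted (constant X?)")
  structure(list(W = W[, seq_len(A), drop = FALSE],
                 P = P[, seq_len(A), drop = FALSE],
                 TT = TT[, seq_len(A), drop = FALSE],
                 q = q[seq_len(A)],
                 nfactors = A, requested = nfactors,
                 x_center = x_center, y_center = y_center),
            class = "plsr_model")
}

#' Regression coefficients of a fitted PLS model
#'
#' Coefficients on the original (uncentred) predictor scale for a nested
#' sub-model with \code{a} factors: \eqn{B_a = W_a (P_a' W_a)^{-1} q_a}.
#'
#' @param object A \code{"plsr_model"}.
#' @param a Number of factors to use (default: all extracted).
#' @return List with \code{coefficients} (length p) and \code{intercept}.
#' @export
plsr_coefficients <- function(object, a = object$nfactors) {
  a <- min(a, object$nfactors)
  W <- object$W[, seq_len(a), drop = FALSE]
  P <- object$P[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W), diag(a))
  b <- drop(R %*% object$q[seq_len(a)])
  list(coefficients = b,
       intercept = object$y_center - sum(object$x_center * b))
}

#' @export
predict.plsr_model <- function(object, newdata, a = object$nfactors, ...) {
  cf <- plsr_coefficients(object, a)
  drop(as.matrix(newdata) %*% cf$coefficients) + cf$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model: %d factor(s), %d predictors>\n",
              x$nfactors, nrow(x$W)))
  invisible(x)
}

#' Leave-one-out RMSE profile over PLS factor counts
#'
#' For each left-out sample the model is refitted from scratch on the
#' remaining samples (centering, and any fold-dependent pre-processing
#' supplied through \code{preprocess}, are re-derived inside the fold) and
#' the held-out sample is predicted with every nested factor count
#' \code{1..f_max} from a single NIPALS pass.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param f_max Largest factor count to profile (capped at
#'   \code{min(f_max, n - 2, p)}).
#' @param preprocess Optional \code{function(X_train, X_test)} returning
#'   \code{list(train =, test =)}; used for fold-internal corrections such as
#'   multiplicative scatter correction against the training mean spectrum.
#' @return List with \code{predictions} (n x f_max matrix of out-of-fold
#'   predictions) and \code{rmse} (per factor count).
#' @export
plsr_loocv_scan <- function(X, y, f_max, preprocess = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out CV needs at least 3 samples")
  f_max <- max(1L, min(f_max, n - 2L, ncol(X)))
  preds <- matrix(NA_real_, n, f_max)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; Xte <- X[i, , drop = FALSE]
    if (!is.null(preprocess)) {
      pp <- preprocess(Xtr, Xte)
      Xtr <- pp$train; Xte <- pp$test
    }
    fit <- tryCatch(fit_plsr(Xtr, y[-i], f_max),
                    error = function(e)
                      stop("fold ", i, " failed: ", conditionMessage(e)))
    for (a in seq_len(f_max))
      preds[i, a] <- predict(fit, Xte, a = a)
  }
  rmse <- sqrt(colMeans((preds - y)^2))
  list(predictions = preds, rmse = rmse, f_max = f_max)
}

#' The strict >2 percent parsimony walk on an RMSE profile
#'
#' Starting from one factor, factor \code{F + 1} is admitted only while
#' \eqn{RMSE_{F+1} < 0.98\, RMSE_F}; a reduction of exactly 2 percent does
#' not qualify.
#'
#' @param rmse Cross-validation RMSE profile indexed by factor count.
#' @return The selected factor count.
#' @export
select_factor_count <- function(rmse) {
  F <- 1L
  while (F + 1L <= length(rmse) && rmse[F + 1L] < 0.98 * rmse[F])
    F <- F + 1L
  F
}

#' Select the number of PLS factors by the >2 percent rule
#'
#' Starting from one factor, an additional factor is admitted only while it
#' reduces the leave-one-out cross-validation RMSE by strictly more than 2
#' percent (\eqn{RMSE_{F+1} < 0.98\, RMSE_F}); an exactly-2-percent reduction
#' does not qualify.
#'
#' @inheritParams plsr_loocv_scan
#' @param center Statistic for the percent-RMSE denominator.
#' @return List with the chosen \code{nfactors}, the \code{cv} result (a
#'   \code{\link{cv_result}}), the full RMSE profile, and the refitted
#'   calibration model.
#' @export
select_plsr_factors <- function(X, y, f_max = 10L, center = c("mean", "median"),
                                preprocess = NULL) {
  center <- match.arg(center)
  scan <- plsr_loocv_scan(X, y, f_max, preprocess = preprocess)
  rmse <- scan$rmse
  F <- select_factor_count(rmse)
  Xall <- X
  if (!is.null(preprocess)) Xall <- preprocess(X, X)$train
  cal <- fit_plsr(Xall, y, F)
  cal_rmse <- sqrt(mean((predict(cal, Xall, a = F) - y)^2))
  cv <- cv_result(y, scan$predictions[, F], complexity = F,
                  center = center, cal_rmse = cal_rmse)
  list(nfactors = F, cv = cv, rmse_profile = rmse, model = cal)
}
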