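test_that("accuracy statistics match hand arithmetic", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  st <- accuracy_stats(y, yhat)
  expect_equal(st$RMSE, sqrt(1 / 3))
  expect_equal(st$R2, 0.5)
  expect_equal(st$pct_RMSE, 100 * sqrt(1 / 3) / 2)
  expect_equal(accuracy_stats(y, y)$R2, 1)
  expect_equal(accuracy_stats(y, y)$RMSE, 0)
  expect_equal(accuracy_stats(y, rep(mean(y), 3))$R2, 0)
  st_med <- accuracy_stats(c(1, 2, 9), c(1, 2, 9) + 1, center = "median")
  expect_equal(st_med$pct_RMSE, 100 * 1 / 2)
  expect_error(accuracy_stats(c(1, 1), c(1, 2)), "zero variance")
})

test_that("OLSR reproduces the normal equations and rejects bad designs", {
  set.seed(41)
  X <- matrix(rnorm(40), 10, 4)
  y <- drop(X %*% c(1, -1, 2, 0.5)) + rnorm(10, 0, 0.1)
  fit <- fit_olsr(X, y)
  D <- cbind(1, X)
  ref <- solve(crossprod(D), crossprod(D, y))
  expect_equal(c(fit$intercept, fit$coefficients), drop(ref),
               ignore_attr = TRUE, tolerance = 1e-8)
  # residuals orthogonal to the predictors
  expect_lt(max(abs(crossprod(D, fit$residuals))), 1e-8)
  # exact linear data: zero residuals
  expect_lt(max(abs(fit_olsr(X, drop(X %*% 1:4) + 2)$residuals)), 1e-9)
  expect_error(fit_olsr(cbind(X, X[, 1]), y), "rank")
  expect_error(fit_olsr(X[1:4, ], y[1:4]), "n >= p")
})

test_that("PLSR equals simple least squares with one predictor and OLSR at full rank", {
  set.seed(43)
  x1 <- matrix(rnorm(12), 12, 1)
  y <- drop(2 + 3 * x1) + rnorm(12, 0, 0.3)
  pl <- fit_plsr(x1, y, 1)
  ls <- fit_olsr(x1, y)
  expect_equal(predict(pl, x1), predict(ls, x1), tolerance = 1e-10)

  X <- matrix(rnorm(12 * 5), 12, 5)
  y2 <- drop(X %*% rnorm(5)) + rnorm(12, 0, 0.2)
  expect_equal(predict(fit_plsr(X, y2, 5), X),
               predict(fit_olsr(X, y2), X), tolerance = 1e-8)
  expect_error(fit_plsr(X, rep(1, 12), 2), "zero-variance")
  expect_error(fit_plsr(X, y2, 12), "nfactors")
})

test_that("PLS scores are orthogonal and calibration RMSE is non-increasing in F", {
  set.seed(47)
  X <- matrix(rnorm(20 * 30), 20, 30)
  y <- drop(X[, 1:4] %*% c(2, -1, 1, 0.5)) + rnorm(20, 0, 0.3)
  fit <- fit_plsr(X, y, 6)
  G <- crossprod(fit$TT)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  cal <- sapply(1:6, function(a) sqrt(mean((predict(fit, X, a = a) - y)^2)))
  expect_true(all(diff(cal) < 1e-12))
})

test_that("PLSR predictions match scikit-learn on random problems", {
  set.seed(53)
  problems <- lapply(1:5, function(k) {
    n <- sample(8:15, 1); p <- sample(3:25, 1)
    X <- matrix(rnorm(n * p), n)
    list(X = X, y = drop(X %*% rnorm(p)) + rnorm(n, 0, 0.2),
         ncomp = sample(seq_len(min(n - 2, p, 5)), 1))
  })
  ref <- sklearn_pls_predict(problems)
  for (k in seq_along(problems)) {
    pr <- problems[[k]]
    fit <- fit_plsr(pr$X, pr$y, pr$ncomp)
    mine <- predict(fit, pr$X, a = pr$ncomp)
    theirs <- unlist(ref[[k]])
    expect_equal(mine, theirs, tolerance = 1e-6)
  }
})

test_that("LOOCV refits every fold, is order-invariant, and is exact on collinear data", {
  X <- matrix(c(0, 1, 2), 3, 1)
  cv <- loocv(X, c(0, 1, 2), fit_olsr)
  expect_equal(cv$RMSE, 0)
  expect_equal(cv$R2, 1)

  # hand-computable folds: y = (0,1,2,10) on x = (0,1,2,3)
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 10)
  hand <- sapply(seq_along(x), function(i) {
    f <- lm(y[-i] ~ x[-i])
    unname(coef(f)[1] + coef(f)[2] * x[i])
  })
  cv2 <- loocv(matrix(x), y, fit_olsr)
  expect_equal(cv2$predictions, hand, tolerance = 1e-10)
  expect_equal(cv2$RMSE, sqrt(mean((y - hand)^2)), tolerance = 1e-10)

  perm <- c(3, 1, 4, 2)
  cv3 <- loocv(matrix(x[perm]), y[perm], fit_olsr)
  expect_equal(cv3$RMSE, cv2$RMSE, tolerance = 1e-12)
  expect_equal(cv3$R2, cv2$R2, tolerance = 1e-12)
})

test_that("factor selection applies the strict >2% rule", {
  expect_identical(select_factor_count(c(10, 9.0, 8.9)), 2L)
  expect_identical(select_factor_count(c(10, 9.9, 9.85, 9.8)), 1L)
  expect_identical(select_factor_count(c(10, 9.8)), 1L)   # exactly 2%: no
  expect_identical(select_factor_count(c(10, 9.79)), 2L)  # just over 2%
  # noiseless rank-2 latent structure is recovered with F = 2
  set.seed(59)
  n <- 16
  t1 <- rnorm(n); t2 <- rnorm(n)
  X <- outer(t1, rnorm(12)) + outer(t2, rnorm(12))
  y <- 3 * t1 - 2 * t2
  sel <- select_plsr_factors(X, y, f_max = 6)
  expect_identical(sel$nfactors, 2L)
  expect_lt(sel$cv$RMSE, 1e-6)
})

test_that("SVR respects the tube, matches OLS for hard fits, absorbs feature scale", {
  # residual spread below epsilon: every point inside the tube
  x <- matrix(seq(0, 1, length.out = 12))
  y <- 1 + 0.5 * x[, 1] + runif(12, -0.05, 0.05)
  fit <- fit_svr_single(x, y, C = 10, epsilon = 0.1)
  expect_true(all(abs(predict(fit, x) - y) <= 0.1 + 1e-6))
  # noiseless line, tiny tube, large C: agrees with OLSR
  y2 <- 2 + 3 * x[, 1]
  s <- fit_svr_single(x, y2, C = 1e5, epsilon = 1e-6)
  expect_lt(max(abs(predict(s, x) - predict(fit_olsr(x, y2), x))), 1e-3)
  # min-max scaling absorbs a tenfold feature rescale
  set.seed(61)
  X <- cbind(runif(15), runif(15))
  y3 <- X[, 1] - 2 * X[, 2] + rnorm(15, 0, 0.05)
  f1 <- fit_svr_single(X, y3, C = 4)
  X10 <- X; X10[, 1] <- 10 * X10[, 1]
  f2 <- fit_svr_single(X10, y3, C = 4)
  expect_equal(predict(f2, X10), predict(f1, X), tolerance = 1e-8)
  expect_error(fit_svr_single(X, y3, C = -1), "positive")
})

test_that("the SVR grid search picks the smallest cost within 2% of the optimum", {
  set.seed(67)
  X <- matrix(runif(18 * 3), 18, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(18, 0, 0.05)
  fit <- fit_svr(X, y, C_grid = 2^(-4:3))
  eligible <- fit$rmse_grid <= 1.02 * min(fit$rmse_grid)
  expect_identical(fit$C, sort(2^(-4:3))[which(eligible)[1]])
  expect_s3_class(fit$cv, "cv_result")
  expect_error(fit_svr(X, y, C_grid = numeric(0)), "empty")
})
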