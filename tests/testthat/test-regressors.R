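# Exhaustive all-pairs KNN oracle, independent of the implementation.
oracle_knr <- function(X, y, Q, k, weighting) {
  apply(Q, 1, function(q) {
    d <- apply(X, 1, function(x) sqrt(sum((x - q)^2)))
    if (any(d == 0)) return(mean(y[d == 0]))
    nn <- sort.list(d, method = "radix")[seq_len(k)]
    if (weighting == "uniform") mean(y[nn])
    else {
      w <- 1 / d[nn]
      sum(w * y[nn]) / sum(w)
    }
  })
}

test_that("the dummy regressor predicts the training mean everywhere", {
  fit <- fit_dummy(c(1, 2, 3))
  expect_equal(predict(fit, matrix(rnorm(10), 5)), rep(2, 5))
  expect_equal(mean(abs(residuals(fit))), mean(abs(c(1, 2, 3) - 2)))
  expect_error(fit_dummy(numeric(0)), "empty")
})

test_that("KNR reproduces hand-worked neighbor averages", {
  X <- matrix(0:2); y <- c(0, 10, 20)
  # query 0.9: neighbors at distances 0.1 (y=10) and 0.9 (y=0)
  expect_equal(fit_predict_knr(X, y, matrix(0.9), k = 2,
                               weighting = "uniform"), 5.0)
  # distance weights 10 and 10/9 -> (10*10 + (10/9)*0) / (10 + 10/9) = 9
  expect_equal(fit_predict_knr(X, y, matrix(0.9), k = 2,
                               weighting = "distance"), 9.0)
  # k = m with uniform weighting is the dummy prediction
  expect_equal(fit_predict_knr(X, y, matrix(5), k = 3,
                               weighting = "uniform"), mean(y))
  # zero-distance neighbors dominate
  expect_equal(fit_predict_knr(X, y, matrix(1), k = 2,
                               weighting = "distance"), 10)
  expect_error(fit_knr(X, y, k = 4), "exceeds")
})

test_that("KNR matches the exhaustive distance-sort oracle", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(5:20, 1); p <- sample(1:4, 1)
    X <- matrix(round(rnorm(m * p), 2), m)   # rounding forces some ties
    y <- rnorm(m)
    Q <- matrix(round(rnorm(3 * p), 2), 3)
    k <- sample(1:m, 1)
    for (w in c("uniform", "distance")) {
      expect_equal(fit_predict_knr(X, y, Q, k, w), oracle_knr(X, y, Q, k, w))
    }
  }
})

test_that("KNR at k = 1 memorizes distinct training points exactly", {
  set.seed(8)
  X <- matrix(rnorm(40), 20)
  y <- rnorm(20)
  expect_equal(fit_predict_knr(X, y, X, k = 1), y)
})

test_that("ridge solves the hand-worked normal equations", {
  # X = [1; -1], y = (1, -1), alpha = 1: beta = (2 + 1)^-1 * 2 = 2/3
  fit <- fit_ridge(matrix(c(1, -1)), c(1, -1), alpha = 1)
  expect_equal(unname(fit$coefficients), 2 / 3)
  expect_equal(fit$intercept, 0)
})

test_that("ridge satisfies stationarity and its limit cases", {
  set.seed(9)
  X <- matrix(rnorm(60), 20); y <- rnorm(20)
  for (alpha in c(0.01, 1, 50)) {
    fit <- fit_ridge(X, y, alpha)
    Xc <- scale(X, scale = FALSE)
    resid <- y - predict(fit, X)
    expect_lt(max(abs(crossprod(Xc, resid) - alpha * fit$coefficients)), 1e-8)
  }
  # alpha = 0 on a full-rank design is ordinary least squares
  ols <- lm.fit(cbind(1, X), y)
  fit0 <- fit_ridge(X, y, 0)
  expect_equal(unname(fit0$coefficients), unname(ols$coefficients[-1]),
               tolerance = 1e-10)
  # alpha = 0, rank-deficient: minimum-norm solution, not a crash
  Xd <- cbind(X, X[, 1])
  fitd <- fit_ridge(Xd, y, 0)
  expect_true(all(is.finite(fitd$coefficients)))
  expect_equal(predict(fitd, Xd), unname(fitted(lm(y ~ X))), tolerance = 1e-8)
  # alpha -> infinity shrinks to the dummy model
  fitb <- fit_ridge(X, y, 1e9)
  expect_lt(max(abs(predict(fitb, X) - mean(y))), 1e-3)
})

test_that("elastic net matches the univariate soft-threshold closed form", {
  set.seed(10)
  m <- 50
  x <- as.numeric(scale(rnorm(m)))
  y <- 2 * x + rnorm(m)
  xc <- x - mean(x); yc <- y - mean(y)
  for (alpha in c(0.05, 0.3, 1)) {
    for (l1 in c(0.2, 0.7, 1)) {
      fit <- fit_elastic_net(matrix(x), y, alpha, l1, tol = 1e-12,
                             max_iter = 1e5)
      z <- sum(xc * yc) / m
      expected <- (sign(z) * max(abs(z) - alpha * l1, 0)) /
        (sum(xc^2) / m + alpha * (1 - l1))
      expect_equal(unname(fit$coefficients), expected, tolerance = 1e-6)
    }
  }
})

test_that("elastic net satisfies the KKT conditions at convergence", {
  set.seed(11)
  m <- 40; p <- 12
  X <- matrix(rnorm(m * p), m)
  y <- drop(X[, 1:3] %*% c(3, -2, 1)) + rnorm(m)
  tol <- 1e-9
  for (pars in list(c(0.1, 0.5), c(0.5, 1), c(0.02, 0.9))) {
    alpha <- pars[1]; l1 <- pars[2]
    fit <- fit_elastic_net(X, y, alpha, l1, tol = tol, max_iter = 1e5)
    Xc <- scale(X, scale = FALSE)
    r <- y - predict(fit, X)
    g <- drop(crossprod(Xc, r)) / m - alpha * (1 - l1) * fit$coefficients
    b <- fit$coefficients
    # active coordinates: gradient equals the L1 subgradient exactly
    expect_lt(max(abs(g[b != 0] - alpha * l1 * sign(b[b != 0])), 0), 10 * tol)
    # inactive coordinates: gradient within the subdifferential
    expect_true(all(abs(g[b == 0]) <= alpha * l1 + 10 * tol))
  }
})

test_that("elastic-net limit cases behave as expected", {
  set.seed(12)
  X <- matrix(rnorm(80), 20); y <- rnorm(20)
  # huge L1 penalty kills every coefficient exactly
  big <- fit_lasso(X, y, alpha = 1e4)
  expect_true(all(big$coefficients == 0))
  expect_equal(predict(big, X), rep(mean(y), 20))
  # l1_ratio = 0 equals ridge under the objective-scaling map
  # alpha_ridge = m * alpha_enet
  m <- nrow(X)
  for (a in c(0.05, 0.5)) {
    en <- fit_elastic_net(X, y, a, l1_ratio = 0, tol = 1e-12, max_iter = 1e5)
    rd <- fit_ridge(X, y, m * a)
    expect_equal(en$coefficients, rd$coefficients, tolerance = 1e-6)
  }
  # non-convergence is flagged, not silent
  expect_warning(f <- fit_elastic_net(X, y, 1e-4, 0.5, tol = 1e-14,
                                      max_iter = 2),
                 "did not converge")
  expect_false(f$converged)
})

test_that("elastic net agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(13)
  m <- 60; p <- 10
  X <- matrix(rnorm(m * p), m)
  y <- drop(X %*% rnorm(p, sd = 0.5)) + rnorm(m)
  # glmnet interprets lambda on an internally y-standardized problem
  # (1/n variance); put y on that scale so the two objectives coincide
  y <- y / sqrt(mean((y - mean(y))^2))
  for (l1 in c(0.5, 1)) {
    for (alpha in c(0.05, 0.2)) {
      mine <- fit_elastic_net(X, y, alpha, l1, tol = 1e-12, max_iter = 1e5)
      ref <- glmnet::glmnet(X, y, alpha = l1, lambda = alpha,
                            standardize = FALSE, thresh = 1e-14)
      expect_equal(unname(mine$coefficients),
                   unname(as.numeric(ref$beta)), tolerance = 1e-4)
    }
  }
})

test_that("error metrics compute MAE, RMSE and NRMSE", {
  em <- error_metrics(c(1, 2), c(0, 3), y_reference_mean = 2)
  expect_equal(em$mae, 1)
  expect_equal(em$rmse, 1)
  expect_equal(em$nrmse, 0.5)
  expect_equal(error_metrics(1:5, 1:5, 3), list(mae = 0, rmse = 0, nrmse = 0))
  # RMSE >= MAE always
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    em <- error_metrics(a, b, 1)
    expect_gte(em$rmse, em$mae)
  }
  expect_error(error_metrics(1:3, 1:4, 1), "equal length")
  expect_error(error_metrics(1:3, 1:3, 0), "reference")
})
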