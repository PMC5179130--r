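#' Native regression estimators
#'
#' The estimators behind the pipeline's headline comparisons are
#' implemented natively: the dummy (training-mean) baseline, k-nearest-
#' neighbor regression, ridge regression, and the lasso / elastic-net
#' family via cyclic coordinate descent. Every fitting function returns a
#' classed object with `predict()`, `print()`, `residuals()` and (for the
#' linear families) `coef()` methods. Other estimator families attach
#' through the plug-in contract of [model_spec()].
#'
#' @name regressors
NULL

as_design <- function(X) {
  if (inherits(X, "abundance_matrix")) X <- X$X
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Dummy (mean) regressor
#'
#' Memorizes the training-mean ADD and predicts it for every input,
#' ignoring the features entirely -- the minimum benchmark every real
#' model must beat.
#'
#' @param y_train numeric response vector (ADD).
#' @return object of class `c("pmi_dummy", "pmi_model")`.
#' @export
fit_dummy <- function(y_train) {
  if (length(y_train) == 0) stop("empty training set", call. = FALSE)
  structure(list(mean = mean(y_train), y_train = y_train),
            class = c("pmi_dummy", "pmi_model"))
}

#' @export
predict.pmi_dummy <- function(object, newdata, ...) {
  n <- if (is.null(dim(newdata))) length(newdata) else nrow(newdata)
  rep(object$mean, n)
}

#' k-nearest-neighbor regression
#'
#' Instance-based: the training rows and their ADD values are stored, and
#' a query is predicted by averaging the ADD of its k nearest training
#' rows under Euclidean distance. `weighting = "uniform"` takes the
#' arithmetic mean; `"distance"` weights neighbor i by 1/d_i, normalized
#' over the k neighbors. If any training row is at distance zero from the
#' query the prediction is the mean ADD of all zero-distance rows. Ties at
#' the k-th neighbor break by training-row order (stable, deterministic).
#'
#' @param X_train training matrix (rows = samples).
#' @param y_train training ADD vector.
#' @param k neighbor count, `1 <= k <= nrow(X_train)` (default 4).
#' @param weighting `"distance"` (default, matching the champion model) or
#'   `"uniform"`.
#' @return object of class `c("pmi_knr", "pmi_model")`.
#' @export
fit_knr <- function(X_train, y_train, k = 4,
                    weighting = c("distance", "uniform")) {
  weighting <- match.arg(weighting)
  X_train <- as_design(X_train)
  if (nrow(X_train) != length(y_train)) stop("X/y size mismatch", call. = FALSE)
  if (k < 1 || k != round(k)) stop("k must be a positive integer", call. = FALSE)
  if (k > nrow(X_train)) {
    stop("k = ", k, " exceeds the ", nrow(X_train), " training instances",
         call. = FALSE)
  }
  structure(list(X = X_train, y = y_train, k = as.integer(k),
                 weighting = weighting),
            class = c("pmi_knr", "pmi_model"))
}

#' @export
predict.pmi_knr <- function(object, newdata, ...) {
  Q <- as_design(newdata)
  if (ncol(Q) != ncol(object$X)) stop("query dimensionality mismatch", call. = FALSE)
  apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(object$X) - q)^2))
    if (any(d == 0)) return(mean(object$y[d == 0]))
    nn <- order(d)[seq_len(object$k)]      # stable order: index breaks ties
    if (object$weighting == "uniform") {
      mean(object$y[nn])
    } else {
      w <- 1 / d[nn]
      sum(w * object$y[nn]) / sum(w)
    }
  })
}

#' Fit-and-predict convenience for k-nearest-neighbor regression
#'
#' @inheritParams fit_knr
#' @param X_query rows to predict.
#' @return predicted ADD for each query row.
#' @export
fit_predict_knr <- function(X_train, y_train, X_query, k = 4,
                            weighting = c("distance", "uniform")) {
  predict(fit_knr(X_train, y_train, k = k, weighting = weighting), X_query)
}

#' Ridge regression (closed form)
#'
#' Minimizes `||y - X beta - b||^2 + alpha ||beta||^2` with an unpenalized
#' intercept, solved in closed form on centered data via the singular
#' value decomposition. At `alpha = 0` on a rank-deficient design the
#' minimum-norm least-squares solution is returned (small singular values
#' dropped), never an error.
#'
#' @param X_train training matrix.
#' @param y_train response vector.
#' @param alpha ridge penalty, `>= 0`.
#' @return object of class `c("pmi_ridge", "pmi_linear", "pmi_model")`
#'   with `coefficients` and `intercept`.
#' @export
fit_ridge <- function(X_train, y_train, alpha) {
  X_train <- as_design(X_train)
  stopifnot_scalar_number(alpha, "alpha", lower = 0)
  xbar <- colMeans(X_train)
  ybar <- mean(y_train)
  Xc <- sweep(X_train, 2, xbar)
  yc <- y_train - ybar
  sv <- svd(Xc)
  d <- sv$d
  if (alpha == 0) {
    keep <- d > max(d[1], 0) * 1e-10
    f <- ifelse(keep, 1 / d, 0)
  } else {
    f <- d / (d^2 + alpha)
  }
  beta <- drop(sv$v %*% (f * crossprod(sv$u, yc)))
  names(beta) <- colnames(X_train)
  structure(list(coefficients = beta,
                 intercept = ybar - drop(crossprod(xbar, beta)),
                 alpha = alpha, X = X_train, y = y_train),
            class = c("pmi_ridge", "pmi_linear", "pmi_model"))
}

#' Elastic-net regression via cyclic coordinate descent
#'
#' Minimizes
#' `1/(2m) ||y - X beta - b||^2 + alpha l1 ||beta||_1
#'  + alpha (1 - l1)/2 ||beta||^2`
#' with an unpenalized intercept, by cyclic coordinate descent with
#' soft-thresholding. Convergence is declared when the largest coefficient
#' change in a sweep drops below `tol`; hitting `max_iter` first raises a
#' warning and sets `converged = FALSE` on the model, never silently.
#' `l1_ratio = 1` is the lasso.
#'
#' @param X_train training matrix.
#' @param y_train response vector.
#' @param alpha overall penalty strength, `>= 0`.
#' @param l1_ratio share of the penalty on the L1 norm, in `[0, 1]`.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter maximum number of full coordinate sweeps.
#' @param beta_init optional warm-start coefficient vector.
#' @return object of class `c("pmi_enet", "pmi_linear", "pmi_model")`.
#' @export
fit_elastic_net <- function(X_train, y_train, alpha, l1_ratio = 0.5,
                            tol = 1e-6, max_iter = 5000, beta_init = NULL) {
  X_train <- as_design(X_train)
  stopifnot_scalar_number(alpha, "alpha", lower = 0)
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0,1]", call. = FALSE)
  m <- nrow(X_train)
  xbar <- colMeans(X_train)
  ybar <- mean(y_train)
  Xc <- sweep(X_train, 2, xbar)
  yc <- y_train - ybar
  p <- ncol(Xc)
  a_j <- colSums(Xc^2) / m                 # per-coordinate curvature
  denom <- a_j + alpha * (1 - l1_ratio)
  lam <- alpha * l1_ratio
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  r <- yc - drop(Xc %*% beta)
  active <- which(a_j > 0)
  converged <- FALSE
  iter <- 0L
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- 0
    for (j in active) {
      bj <- beta[j]
      zj <- sum(Xc[, j] * r) / m + a_j[j] * bj
      bnew <- soft(zj, lam) / denom[j]
      if (bnew != bj) {
        r <- r - Xc[, j] * (bnew - bj)
        beta[j] <- bnew
        delta <- max(delta, abs(bnew - bj))
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("elastic net did not converge in ", max_iter,
            " sweeps (last max change ", signif(delta, 3), ")", call. = FALSE)
  }
  names(beta) <- colnames(X_train)
  structure(list(coefficients = beta,
                 intercept = ybar - drop(crossprod(xbar, beta)),
                 alpha = alpha, l1_ratio = l1_ratio,
                 converged = converged, n_iter = iter,
                 X = X_train, y = y_train),
            class = c("pmi_enet", "pmi_linear", "pmi_model"))
}

#' Lasso regression
#'
#' [fit_elastic_net()] with `l1_ratio = 1`.
#'
#' @inheritParams fit_elastic_net
#' @return object of class `c("pmi_enet", "pmi_linear", "pmi_model")`.
#' @export
fit_lasso <- function(X_train, y_train, alpha, tol = 1e-6, max_iter = 5000) {
  fit_elastic_net(X_train, y_train, alpha, l1_ratio = 1,
                  tol = tol, max_iter = max_iter)
}

#' @export
predict.pmi_linear <- function(object, newdata, ...) {
  X <- as_design(newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
coef.pmi_linear <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.pmi_model <- function(object, ...) {
  object$y - predict(object, object$X)
}

#' @export
residuals.pmi_dummy <- function(object, ...) {
  object$y_train - object$mean
}

#' @export
print.pmi_model <- function(x, ...) {
  cls <- class(x)[1]
  cat("<", cls, ">", sep = "")
  if (cls == "pmi_dummy") cat(" mean =", signif(x$mean, 5))
  if (cls == "pmi_knr") cat(" k =", x$k, ", weighting =", x$weighting,
                            ", m =", nrow(x$X))
  if (cls == "pmi_ridge") cat(" alpha =", x$alpha, ",",
                              sum(x$coefficients != 0), "nonzero coef")
  if (cls == "pmi_enet") cat(" alpha =", x$alpha, ", l1_ratio =", x$l1_ratio,
                             ",", sum(x$coefficients != 0), "nonzero coef",
                             if (!x$converged) "(NOT converged)")
  cat("\n")
  invisible(x)
}

#' Regression error metrics
#'
#' Mean absolute error, root mean squared error, and the normalized RMSE:
#' RMSE divided by `y_reference_mean`, the mean ADD over the entire
#' dataset (train and test) for the body site, which makes scores
#' comparable across datasets.
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @param y_reference_mean positive reference mean ADD.
#' @return list with `mae`, `rmse`, `nrmse`.
#' @export
error_metrics <- function(y_true, y_pred, y_reference_mean) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (y_reference_mean <= 0) stop("y_reference_mean must be > 0", call. = FALSE)
  d <- y_true - y_pred
  rmse <- sqrt(mean(d^2))
  list(mae = mean(abs(d)), rmse = rmse, nrmse = rmse / y_reference_mean)
}
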