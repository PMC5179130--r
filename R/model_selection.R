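#' Model specifications and the plug-in contract
#'
#' A `model_spec` names an estimator family and its hyperparameters. The
#' native families are `dummy`, `knr`, `ridge`, `lasso` and `elastic_net`;
#' `plugin` attaches any external estimator through a
#' `fit(X, y) -> object with predict(object, X)` contract, which is how
#' families such as support-vector or random-forest regression join the
#' evaluation harness without being reimplemented.
#'
#' @param family one of `"dummy"`, `"knr"`, `"ridge"`, `"lasso"`,
#'   `"elastic_net"`, `"plugin"`.
#' @param ... named hyperparameters (`k`, `weighting`, `alpha`,
#'   `l1_ratio`, ...; for `plugin`: `fit`, a function, and `label`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("dummy", "knr", "ridge", "lasso",
                                  "elastic_net", "plugin"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  if (family == "knr" && !is.null(hp$k) &&
      (hp$k < 1 || hp$k != round(hp$k))) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (!is.null(hp$alpha) && hp$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!is.null(hp$l1_ratio) && (hp$l1_ratio < 0 || hp$l1_ratio > 1)) {
    stop("l1_ratio must be in [0,1]", call. = FALSE)
  }
  if (family == "plugin" && !is.function(hp$fit)) {
    stop("plugin specs need a fit(X, y) function", call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- x$hyperparameters[!vapply(x$hyperparameters, is.function, logical(1))]
  cat("<model_spec>", x$family,
      if (length(hp)) paste0("(", paste(names(hp), unlist(hp), sep = "=",
                                        collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Serialize a model spec to/from JSON
#'
#' Dialect: `{"family": ..., "hyperparameters": {...}}`. Plug-in function
#' objects are not serialized (their `label` is).
#'
#' @param spec a [model_spec()].
#' @return `model_spec_json`: a JSON string; `model_spec_from_json`: a
#'   [model_spec()].
#' @export
model_spec_json <- function(spec) {
  hp <- spec$hyperparameters
  hp <- hp[!vapply(hp, is.function, logical(1))]
  jsonlite::toJSON(list(family = spec$family, hyperparameters = hp),
                   auto_unbox = TRUE)
}

#' @rdname model_spec_json
#' @param json a JSON string from `model_spec_json()`.
#' @export
model_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(model_spec, c(list(family = x$family), as.list(x$hyperparameters)))
}

#' Fit a model spec to data
#'
#' Dispatches to the native fitting functions or to the plug-in `fit`.
#'
#' @param spec a [model_spec()].
#' @param X training matrix (or [abundance_matrix]).
#' @param y training ADD vector.
#' @return a fitted model with a `predict` method.
#' @export
fit_model <- function(spec, X, y) {
  hp <- spec$hyperparameters
  switch(spec$family,
    dummy = fit_dummy(y),
    knr = fit_knr(X, y,
                  k = if (is.null(hp$k)) 4 else hp$k,
                  weighting = if (is.null(hp$weighting)) "distance"
                              else hp$weighting),
    ridge = fit_ridge(X, y, alpha = hp$alpha),
    lasso = fit_lasso(X, y, alpha = hp$alpha,
                      tol = if (is.null(hp$tol)) 1e-4 else hp$tol,
                      max_iter = if (is.null(hp$max_iter)) 2000 else hp$max_iter),
    elastic_net = fit_elastic_net(X, y, alpha = hp$alpha,
                                  l1_ratio = if (is.null(hp$l1_ratio)) 0.5
                                             else hp$l1_ratio,
                                  tol = if (is.null(hp$tol)) 1e-4 else hp$tol,
                                  max_iter = if (is.null(hp$max_iter)) 2000
                                             else hp$max_iter),
    plugin = hp$fit(as_design(X), y))
}

#' Deterministic 80/20 train/test split
#'
#' The split depends only on the sample count and the seed, never on
#' feature content, so every dataset variant of the same samples shares
#' one split. The training set holds `round(train_fraction * m)` indices
#' drawn uniformly at random.
#'
#' @param m sample count, `>= 5`.
#' @param seed integer seed.
#' @param train_fraction training share (default 0.8).
#' @return list with integer vectors `train` and `test` (sorted, disjoint,
#'   exhaustive).
#' @export
make_split <- function(m, seed, train_fraction = 0.8) {
  if (m < 5) stop("need at least 5 samples to split", call. = FALSE)
  n_train <- round(train_fraction * m)
  train <- with_seed(seed, sort(sample.int(m, n_train)))
  list(train = train, test = setdiff(seq_len(m), train))
}

#' Partition training indices into k folds
#'
#' Disjoint, exhaustive folds whose sizes differ by at most one,
#' deterministic given the seed.
#'
#' @param train_idx integer vector of training row indices.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @return list of `folds` integer vectors.
#' @export
kfold_partition <- function(train_idx, folds = 10, seed) {
  n <- length(train_idx)
  if (folds > n) stop("more folds than training instances", call. = FALSE)
  shuffled <- with_seed(seed + 1L, sample(train_idx))
  split(shuffled, rep(seq_len(folds), length.out = n))
}

#' Cross-validate one model specification
#'
#' For each fold, fits the spec on the complement of the fold within the
#' training rows and scores mean absolute error on the held-out fold; the
#' fold scores p_1..p_k are averaged into the training (cross-validation)
#' error. A fold configuration on which fitting is impossible (e.g. k
#' exceeding the complement size) marks the spec infeasible rather than
#' imputing a score.
#'
#' @param spec a [model_spec()].
#' @param X,y data; folds index rows of `X`.
#' @param folds list of held-out index vectors (see [kfold_partition()]).
#' @return object of class `cv_score`: list with `fold_errors`,
#'   `mean_error`, `infeasible`.
#' @export
cross_validate <- function(spec, X, y, folds) {
  X <- as_design(X)
  all_idx <- sort(unlist(folds))
  fold_errors <- numeric(length(folds))
  for (i in seq_along(folds)) {
    held <- folds[[i]]
    rest <- setdiff(all_idx, held)
    if (spec$family == "knr") {
      k <- spec$hyperparameters$k
      if (!is.null(k) && k > length(rest)) {
        return(structure(list(fold_errors = NULL, mean_error = Inf,
                              infeasible = TRUE), class = "cv_score"))
      }
    }
    fit <- suppressWarnings(fit_model(spec, X[rest, , drop = FALSE], y[rest]))
    pred <- predict(fit, X[held, , drop = FALSE])
    fold_errors[i] <- mean(abs(y[held] - pred))
  }
  structure(list(fold_errors = fold_errors,
                 mean_error = mean(fold_errors), infeasible = FALSE),
            class = "cv_score")
}

#' Default hyperparameter grids
#'
#' KNR: k in 1..10 crossed with uniform/distance weighting; ridge and
#' lasso: 13 log-spaced penalties over `10^-3 .. 10^3`; elastic net: the
#' same penalties crossed with `l1_ratio` in {0.1, 0.5, 0.9}.
#'
#' @return named list: family -> named list of hyperparameter value
#'   vectors.
#' @export
default_hypergrid <- function() {
  alphas <- 10^seq(-3, 3, by = 0.5)
  list(dummy = list(),
       knr = list(k = 1:10, weighting = c("uniform", "distance")),
       ridge = list(alpha = alphas),
       lasso = list(alpha = alphas),
       elastic_net = list(alpha = alphas, l1_ratio = c(0.1, 0.5, 0.9)))
}

#' Enumerate the model specs of a family's grid
#'
#' Cartesian product of the hyperparameter value vectors, in column-major
#' `expand.grid` order (the deterministic tie-break order of
#' [grid_search()]).
#'
#' @param family estimator family name.
#' @param grid named list of hyperparameter value vectors for that family
#'   (may be empty).
#' @return list of [model_spec()] objects.
#' @export
grid_points <- function(family, grid) {
  if (length(grid) == 0) return(list(model_spec(family)))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    do.call(model_spec, c(list(family = family), as.list(combos[i, , drop = FALSE])))
  })
}

#' Exhaustive grid search by cross-validated error
#'
#' Evaluates every grid point with [cross_validate()] on the training rows
#' only and returns the spec with the lowest mean error; ties keep the
#' first point in grid order. Infeasible points are excluded; all points
#' infeasible is an error.
#'
#' @param family estimator family.
#' @param grid named list of hyperparameter values (see
#'   [default_hypergrid()]).
#' @param X_train,y_train training rows only; the test set never enters.
#' @param folds fold partition of `seq_len(nrow(X_train))` rows (local
#'   indices into the training set).
#' @return list with `spec` (best [model_spec()]) and `cv` (its
#'   `cv_score`).
#' @export
grid_search <- function(family, grid, X_train, y_train, folds) {
  specs <- grid_points(family, grid)
  best <- NULL
  best_cv <- NULL
  for (spec in specs) {
    cv <- cross_validate(spec, X_train, y_train, folds)
    if (cv$infeasible) next
    if (is.null(best) || cv$mean_error < best_cv$mean_error) {
      best <- spec
      best_cv <- cv
    }
  }
  if (is.null(best)) stop("every grid point was infeasible", call. = FALSE)
  list(spec = best, cv = best_cv)
}

#' Evaluate a tuned model on the held-out test set
#'
#' Retrains the spec on the full training set, predicts the test set, and
#' assembles a leaderboard entry: the training (cross-validation) error,
#' the test mean absolute error, and the normalized RMSE (test RMSE over
#' the mean ADD of the whole dataset for the site).
#'
#' @param spec tuned [model_spec()].
#' @param X_train,y_train,X_test,y_test disjoint train/test data.
#' @param y_reference_mean mean ADD over the entire dataset for this site.
#' @param dataset dataset id string (see [dataset_id()]).
#' @param training_error the spec's cross-validated training error.
#' @return one-row data frame with columns `training_error`, `nrmse`,
#'   `regressor`, `test_error`, `dataset`, `hyperparameters`.
#' @export
evaluate_model <- function(spec, X_train, y_train, X_test, y_test,
                           y_reference_mean, dataset = NA_character_,
                           training_error = NA_real_) {
  fit <- suppressWarnings(fit_model(spec, X_train, y_train))
  pred <- predict(fit, as_design(X_test))
  em <- error_metrics(y_test, pred, y_reference_mean)
  label <- if (spec$family == "plugin" &&
               !is.null(spec$hyperparameters$label)) {
    spec$hyperparameters$label
  } else toupper(spec$family)
  data.frame(training_error = training_error, nrmse = em$nrmse,
             regressor = label, test_error = em$mae, dataset = dataset,
             hyperparameters = as.character(model_spec_json(spec)),
             stringsAsFactors = FALSE)
}

#' Rank leaderboard entries
#'
#' Ascending by the chosen error column, stable on ties, truncated to
#' `top_n` rows (the published tables list ten).
#'
#' @param entries data frame of [evaluate_model()] rows.
#' @param rank_by `"training_error"` (the conservative protocol) or
#'   `"test_error"` (validation-ranked selection).
#' @param top_n rows to keep (default 10).
#' @return the ordered, truncated data frame.
#' @export
build_leaderboard <- function(entries,
                              rank_by = c("training_error", "test_error"),
                              top_n = 10) {
  rank_by <- match.arg(rank_by)
  if (nrow(entries) == 0) stop("no leaderboard entries", call. = FALSE)
  ord <- order(entries[[rank_by]])           # stable
  utils::head(entries[ord, , drop = FALSE], top_n)
}

#' Write a leaderboard TSV in the published column order
#'
#' Columns: Training error, NRMSE, Regressor, Test error, Dataset.
#'
#' @param entries leaderboard data frame.
#' @param path output path.
#' @param header_lines optional comment lines (seed, config hash, ...)
#'   written before the table, prefixed `#`.
#' @export
write_leaderboard <- function(entries, path, header_lines = character()) {
  out <- data.frame(`Training error` = round(entries$training_error, 2),
                    NRMSE = round(entries$nrmse, 2),
                    Regressor = entries$regressor,
                    `Test error` = round(entries$test_error, 2),
                    Dataset = entries$dataset,
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
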