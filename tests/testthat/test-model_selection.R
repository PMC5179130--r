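test_that("the 80/20 split is deterministic, exhaustive and uniform", {
  sp <- make_split(10, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(make_split(10, seed = 1), sp)
  expect_false(identical(make_split(10, seed = 2), sp))
  expect_error(make_split(4, seed = 1), "at least 5")

  # each index lands in the test set about 20% of the time
  m <- 67
  counts <- numeric(m)
  for (seed in 1:2000) {
    counts[make_split(m, seed)$test] <- counts[make_split(m, seed)$test] + 1
  }
  rate <- length(make_split(m, 1)$test) / m   # 13/67, the ~20% share
  expect_true(all(abs(counts / 2000 - rate) < 0.03))
})

test_that("k-fold partitions cover the training set in near-equal folds", {
  folds <- kfold_partition(1:50, folds = 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(unname(sort(lengths(folds))), rep(5, 10))
  expect_setequal(unlist(folds), 1:50)

  folds53 <- kfold_partition(1:53, folds = 10, seed = 3)
  expect_equal(unname(sort(lengths(folds53), decreasing = TRUE)),
               c(6, 6, 6, 5, 5, 5, 5, 5, 5, 5))
  expect_setequal(unlist(folds53), 1:53)
  expect_identical(kfold_partition(1:53, folds = 10, seed = 3), folds53)
  expect_error(kfold_partition(1:5, folds = 10, seed = 1), "more folds")
})

test_that("cross-validation scores the dummy model by direct recomputation", {
  set.seed(20)
  X <- matrix(rnorm(60), 30)
  y <- runif(30, 0, 500)
  folds <- kfold_partition(1:30, folds = 5, seed = 4)
  cv <- cross_validate(model_spec("dummy"), X, y, folds)
  manual <- vapply(folds, function(f) {
    mean(abs(y[f] - mean(y[-f])))
  }, numeric(1))
  expect_equal(cv$fold_errors, unname(manual))
  expect_equal(cv$mean_error, mean(manual))

  # a stub that predicts perfectly on any input scores zero
  y_det <- rowSums(X)   # deterministic target the stub knows
  stub <- model_spec("plugin", fit = function(X, y) {
    structure(list(), class = "oracle_stub")
  }, label = "ORACLE")
  assign("predict.oracle_stub",
         function(object, newdata, ...) rowSums(newdata),
         envir = globalenv())
  on.exit(rm("predict.oracle_stub", envir = globalenv()))
  cv0 <- cross_validate(stub, X, y_det, folds)
  expect_equal(cv0$mean_error, 0)

  # permutation invariance of the fold order
  cv_perm <- cross_validate(model_spec("dummy"), X, y, rev(folds))
  expect_equal(cv_perm$mean_error, cv$mean_error)

  # infeasible configurations are flagged, not scored
  cvk <- cross_validate(model_spec("knr", k = 29), X, y, folds)
  expect_true(cvk$infeasible)
})

test_that("grid search equals exhaustive enumeration and breaks ties first", {
  set.seed(21)
  X <- matrix(rnorm(80), 40)
  y <- drop(X %*% c(2, -1)) + rnorm(40, sd = 0.3) + 10
  folds <- kfold_partition(1:40, folds = 5, seed = 5)
  grid <- list(k = 1:6, weighting = c("uniform", "distance"))
  gs <- grid_search("knr", grid, X, y, folds)
  # oracle: recompute every grid point independently
  all_cv <- vapply(grid_points("knr", grid), function(spec) {
    cross_validate(spec, X, y, folds)$mean_error
  }, numeric(1))
  expect_equal(gs$cv$mean_error, min(all_cv))
  best_idx <- which.min(all_cv)
  expect_equal(gs$spec$hyperparameters$k,
               grid_points("knr", grid)[[best_idx]]$hyperparameters$k)

  # single-point grid returns that point
  one <- grid_search("ridge", list(alpha = 2), X, y, folds)
  expect_equal(one$spec$hyperparameters$alpha, 2)
  # all-infeasible grid errors
  expect_error(grid_search("knr", list(k = 1000), X, y, folds), "infeasible")
})

test_that("grid search adapts k to the local structure of the data", {
  smooth_wins <- 0; noise_wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    m <- 50
    x <- sort(runif(m, 0, 10))
    X <- matrix(x)
    folds <- kfold_partition(1:m, folds = 5, seed = seed)
    grid <- list(k = c(1, 2, 15, 20), weighting = "uniform")
    # strong local structure: small k should win
    y_local <- sin(3 * x) * 5 + rnorm(m, sd = 0.1)
    k_local <- grid_search("knr", grid, X, y_local,
                           folds)$spec$hyperparameters$k
    # pure noise: large k should win
    y_noise <- rnorm(m)
    k_noise <- grid_search("knr", grid, X, y_noise,
                           folds)$spec$hyperparameters$k
    smooth_wins <- smooth_wins + (k_local <= 2)
    noise_wins <- noise_wins + (k_noise >= 15)
  }
  expect_gt(smooth_wins, 10)
  expect_gt(noise_wins, 10)
})

test_that("grid search never touches the test rows", {
  set.seed(22)
  X <- matrix(rnorm(100), 50)
  y <- drop(X %*% c(1, 2)) + rnorm(50, sd = 0.2)
  sp <- make_split(50, seed = 6)
  folds <- kfold_partition(seq_along(sp$train), folds = 5, seed = 6)
  grid <- list(k = c(1, 3, 5), weighting = c("uniform", "distance"))
  pick1 <- grid_search("knr", grid, X[sp$train, ], y[sp$train], folds)
  # poison the test rows; the selection must be identical
  X2 <- X; X2[sp$test, ] <- 1e6
  y2 <- y; y2[sp$test] <- -1e6
  pick2 <- grid_search("knr", grid, X2[sp$train, ], y2[sp$train], folds)
  expect_identical(pick1$spec, pick2$spec)
  expect_identical(pick1$cv$mean_error, pick2$cv$mean_error)
})

test_that("evaluate_model reports test error and NRMSE from a full retrain", {
  set.seed(23)
  X <- matrix(rnorm(60), 30); y <- runif(30, 0, 400)
  sp <- make_split(30, seed = 7)
  entry <- evaluate_model(model_spec("dummy"),
                          X[sp$train, ], y[sp$train],
                          X[sp$test, ], y[sp$test],
                          y_reference_mean = mean(y),
                          dataset = "GENUS_NONCURATED_JOINT",
                          training_error = 12.3)
  expect_equal(entry$test_error,
               mean(abs(y[sp$test] - mean(y[sp$train]))))
  expect_equal(entry$nrmse,
               sqrt(mean((y[sp$test] - mean(y[sp$train]))^2)) / mean(y))
  expect_equal(entry$training_error, 12.3)
  expect_equal(entry$regressor, "DUMMY")

  # leaderboard rows survive the TSV writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_leaderboard(entry, path, header_lines = "seed=7")
  back <- read.delim(path, comment.char = "#", check.names = FALSE)
  expect_equal(back$Dataset, "GENUS_NONCURATED_JOINT")
  expect_equal(back$`Test error`, round(entry$test_error, 2))
})

test_that("leaderboards rank by the requested error, stably", {
  entries <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(training_error = c(3, 1, 2)[i], nrmse = 0.5,
               regressor = "KNR", test_error = c(5, 6, 4)[i],
               dataset = paste0("D", i), hyperparameters = "{}",
               stringsAsFactors = FALSE)
  }))
  by_train <- build_leaderboard(entries, "training_error")
  expect_equal(by_train$training_error, c(1, 2, 3))
  by_test <- build_leaderboard(entries, "test_error", top_n = 2)
  expect_equal(by_test$dataset, c("D3", "D1"))
  expect_error(build_leaderboard(entries[0, ]), "no leaderboard")
})

test_that("model specs round-trip through JSON", {
  spec <- model_spec("knr", k = 4, weighting = "distance")
  expect_equal(model_spec_from_json(model_spec_json(spec)), spec)
  spec2 <- model_spec("elastic_net", alpha = 0.5, l1_ratio = 0.9)
  expect_equal(model_spec_from_json(model_spec_json(spec2)), spec2)
  expect_error(model_spec("knr", k = 0.5), "positive integer")
  expect_error(model_spec("ridge", alpha = -1), "alpha")
})
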