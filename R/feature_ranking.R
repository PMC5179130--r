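#' Feature ranking for ADD prediction
#'
#' Three complementary rankings of taxa by predictive relevance for ADD:
#' a univariate F-test on the single-feature linear fit, a bootstrap
#' ensemble of regression trees scored by impurity-decrease importance,
#' and a nearest-neighbor estimate of the mutual information between each
#' taxon's abundance and ADD. The tree and mutual-information scores can
#' detect relationships more complex than linear correlation.
#'
#' All three return a `feature_scores` object: list with `method`,
#' `scores` (named per-feature values: p-values for the F-test, normalized
#' importances for trees, nats for MI) and `ranking` (feature names,
#' best first, stable on ties).
#'
#' @name feature_ranking
NULL

new_feature_scores <- function(method, scores, decreasing) {
  ord <- order(scores, decreasing = decreasing)   # stable
  structure(list(method = method, scores = scores,
                 ranking = names(scores)[ord]),
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, n = 5, ...) {
  cat("<feature_scores> method=", x$method, ", ", length(x$scores),
      " features; top ", n, ":\n", sep = "")
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  for (f in top) cat("  ", f, " (", signif(x$scores[f], 3), ")\n", sep = "")
  invisible(x)
}

#' Univariate F-test feature scores
#'
#' Each feature is fit alone against ADD in a linear model; the returned
#' p-value is the probability of the observed coefficient under the null
#' that it is zero. Computed through the correlation identity
#' `F = r^2 (n-2) / (1-r^2)` on (1, n-2) degrees of freedom, which makes
#' the ranking identical to ranking by absolute Pearson correlation.
#' Constant features get p = 1 and rank last.
#'
#' @param X matrix or [abundance_matrix].
#' @param y ADD vector (defaults to `X$y`).
#' @return a `feature_scores` object (scores are p-values, ascending
#'   ranking).
#' @export
f_value_scores <- function(X, y = NULL) {
  if (inherits(X, "abundance_matrix")) { if (is.null(y)) y <- X$y; X <- X$X }
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  p <- apply(X, 2, function(col) {
    if (stats::sd(col) == 0) return(1)
    r <- stats::cor(col, y)
    if (abs(r) >= 1) return(.Machine$double.xmin)
    f <- r^2 * (n - 2) / (1 - r^2)
    max(stats::pf(f, 1, n - 2, lower.tail = FALSE), .Machine$double.xmin)
  })
  names(p) <- colnames(X)
  new_feature_scores("f_value", p, decreasing = FALSE)
}

# Kraskov-type k-nearest-neighbor mutual information between two
# continuous variables (first KSG estimator), in nats. Exhaustive O(m^2)
# neighbor counting; adequate at this package's sample sizes.
ksg_mi <- function(x, y, k = 3) {
  m <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  nx <- numeric(m); ny <- numeric(m)
  for (i in seq_len(m)) {
    eps <- sort(dz[i, ], partial = k)[k]
    nx[i] <- sum(dx[i, -i] < eps)
    ny[i] <- sum(dy[i, -i] < eps)
  }
  digamma(k) + digamma(m) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Mutual-information feature scores
#'
#' Estimates the mutual information (nats) between each feature and ADD
#' with the continuous-continuous k-nearest-neighbor (Kraskov-type)
#' estimator. Inputs are standardized and perturbed with seeded noise at
#' 1e-10 scale to break the exact ties that degenerate the neighbor
#' counts; negative estimates are clipped to zero. The estimator is
#' invariant (up to estimation noise) under strictly monotone rescaling
#' of a feature.
#'
#' @param X matrix or [abundance_matrix].
#' @param y ADD vector (defaults to `X$y`).
#' @param neighbors neighbor count k (default 3).
#' @param seed seed for the tie-breaking jitter.
#' @return a `feature_scores` object (scores in nats, descending ranking).
#' @export
mutual_information_scores <- function(X, y = NULL, neighbors = 3, seed = 1) {
  if (inherits(X, "abundance_matrix")) { if (is.null(y)) y <- X$y; X <- X$X }
  m <- nrow(X)
  if (m <= neighbors) stop("need more samples than neighbors", call. = FALSE)
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
  mi <- with_seed(seed, {
    ys <- std(y) + stats::rnorm(m, sd = 1e-10)
    apply(X, 2, function(col) {
      if (stats::sd(col) == 0) return(0)
      xs <- std(col) + stats::rnorm(m, sd = 1e-10)
      max(ksg_mi(xs, ys, k = neighbors), 0)
    })
  })
  names(mi) <- colnames(X)
  new_feature_scores("mutual_information", mi, decreasing = TRUE)
}

#' Tree-ensemble feature importances
#'
#' Fits an ensemble of CART regression trees on bootstrap resamples and
#' scores each feature by its total impurity (variance) decrease across
#' the ensemble, normalized to sum to one. Backed by
#' [randomForest::randomForest()] with `nodesize = 2`; `mtry` defaults to
#' all features so the split chosen at every node is the deterministic
#' best over the full feature set.
#'
#' @param X matrix or [abundance_matrix].
#' @param y ADD vector (defaults to `X$y`).
#' @param n_trees ensemble size (default 100).
#' @param max_depth optional depth cap (mapped to a node-count cap);
#'   `NULL` grows trees to the `nodesize` limit.
#' @param seed RNG seed; the result is deterministic given it.
#' @param mtry features tried per split; default all.
#' @return a `feature_scores` object (normalized importances, descending
#'   ranking).
#' @export
tree_importance_scores <- function(X, y = NULL, n_trees = 100,
                                   max_depth = NULL, seed = 1, mtry = NULL) {
  if (inherits(X, "abundance_matrix")) { if (is.null(y)) y <- X$y; X <- X$X }
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  maxnodes <- if (is.null(max_depth)) NULL else 2^max_depth
  if (is.null(mtry)) mtry <- ncol(X)
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  rf <- with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               nodesize = 2, mtry = mtry,
                               maxnodes = maxnodes, importance = FALSE))
  imp <- rf$importance[, "IncNodePurity"]
  total <- sum(imp)
  imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(X)
  new_feature_scores("tree", imp, decreasing = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-method top-k consensus
#'
#' For each ranking method, takes the top `k` features; the consensus
#' count of a feature is the number of methods placing it in their top k.
#' Phyla flagged by all three methods are the strongest candidate
#' indicator taxa.
#'
#' @param tables list of `feature_scores` objects over the same feature
#'   universe.
#' @param k listing depth (default 5); capped with a warning if it
#'   exceeds the feature count.
#' @return data frame with `feature`, `consensus` (methods count), and
#'   one rank column per method (NA if outside that method's top k),
#'   ordered by descending consensus then best rank.
#' @export
top_k_consensus <- function(tables, k = 5) {
  stopifnot(length(tables) >= 1)
  universe <- tables[[1]]$ranking
  for (t in tables) {
    if (!setequal(t$ranking, universe)) {
      stop("rankings cover different feature universes", call. = FALSE)
    }
  }
  if (k > length(universe)) {
    warning("k capped to the ", length(universe), " available features",
            call. = FALSE)
    k <- length(universe)
  }
  tops <- lapply(tables, function(t) t$ranking[seq_len(k)])
  feats <- unique(unlist(tops))
  methods <- vapply(tables, function(t) t$method, character(1))
  ranks <- sapply(tops, function(top) match(feats, top))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = length(feats))
  colnames(ranks) <- methods
  out <- data.frame(feature = feats,
                    consensus = rowSums(!is.na(ranks)),
                    ranks, check.names = FALSE,
                    stringsAsFactors = FALSE)
  best <- apply(ranks, 1, min, na.rm = TRUE)
  out[order(-out$consensus, best), , drop = FALSE]
}
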