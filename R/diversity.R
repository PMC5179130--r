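#' Hill diversity of order q
#'
#' The Hill number of order q is the effective number of equally abundant
#' taxa in a composition p_1..p_S:
#' \deqn{{}^qD = \left(\sum_{p_i > 0} p_i^q\right)^{1/(1-q)}}
#' It is the reciprocal of the weighted power mean (power q - 1) of the
#' proportions. Special orders recover classical indices: q = 0 is species
#' richness, q -> 1 is exp of the Shannon entropy H' = -sum p_i ln p_i,
#' and q = 2 is the inverse Simpson index 1 / sum p_i^2. Low q emphasizes
#' richness, high q emphasizes equitability.
#'
#' Compositions are renormalized internally (joint ear+nose rows sum to 2
#' by construction; the same organism at the two sites counts as two taxa).
#' Zero proportions are excluded from the power sums.
#'
#' @param p nonnegative proportions; any positive total is accepted and
#'   renormalized.
#' @param q diversity order, a single number >= 0.
#' @return the effective number of taxa, in `[1, S]`.
#' @export
hill_diversity <- function(p, q) {
  stopifnot_scalar_number(q, "q")
  if (q < 0) stop("diversity order q must be >= 0", call. = FALSE)
  if (any(p < 0) || !any(p > 0)) {
    stop("composition must be nonnegative with positive total", call. = FALSE)
  }
  p <- p[p > 0]
  p <- p / sum(p)
  if (abs(q - 1) < 1e-9) {
    return(exp(-sum(p * log(p))))
  }
  if (q == 0) return(length(p))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample diversity of an abundance matrix
#'
#' @param X an [abundance_matrix] or a numeric matrix of row compositions.
#' @param q diversity order.
#' @return numeric vector, one effective number per row, row order kept.
#' @export
diversity_vector <- function(X, q) {
  if (inherits(X, "abundance_matrix")) X <- X$X
  apply(X, 1, hill_diversity, q = q)
}

#' Pearson correlation with two-tailed significance
#'
#' The p-value uses the exact closed form under the null of no
#' correlation: t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom,
#' two-tailed.
#'
#' @param x,y numeric vectors of equal length n >= 3, both nonconstant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, p_value = pearson_p(r, n), n = n)
}

#' @rdname pearson_r_p
#' @param r a correlation coefficient in `[-1, 1]`.
#' @param n the sample size behind it.
#' @return `pearson_p`: the two-tailed p-value, clamped into `(0, 1]`.
#' @export
pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  max(2 * stats::pt(-t, df = n - 2), .Machine$double.xmin)
}

#' Scan the diversity order q for the strongest ADD correlation
#'
#' Evaluates the Pearson correlation between per-sample Hill diversity and
#' ADD at every order in `q_grid` and returns the order with the smallest
#' two-tailed p-value (equivalently the largest absolute r at fixed n).
#' Grid points where the diversity vector is constant are skipped; ties
#' keep the first grid point.
#'
#' @param X an [abundance_matrix] (its `y` is used when `y` is missing) or
#'   numeric matrix.
#' @param y ADD vector; defaults to `X$y`.
#' @param q_grid diversity orders to scan; the default covers `[0, 5]`
#'   with 200 evenly spaced points.
#' @return an object of class `q_scan`: list with `q_star`, `r`,
#'   `p_value`, `n` and the full `curve` data frame (q, r, p).
#' @export
q_scan <- function(X, y = NULL, q_grid = seq(0, 5, length.out = 200)) {
  if (inherits(X, "abundance_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  if (is.null(y)) stop("ADD vector y required", call. = FALSE)
  if (length(q_grid) == 0) stop("q_grid must be nonempty", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 samples", call. = FALSE)
  curve <- data.frame(q = q_grid, r = NA_real_, p = NA_real_)
  for (i in seq_along(q_grid)) {
    d <- diversity_vector(X, q_grid[i])
    if (stats::sd(d) == 0) next
    rp <- pearson_r_p(d, y)
    curve$r[i] <- rp$r
    curve$p[i] <- rp$p_value
  }
  if (all(is.na(curve$p))) {
    stop("diversity vector constant at every q; correlation undefined",
         call. = FALSE)
  }
  best <- which.min(curve$p)   # first index on ties
  structure(list(q_star = curve$q[best], r = curve$r[best],
                 p_value = curve$p[best], n = nrow(X), curve = curve),
            class = "q_scan")
}

#' @export
print.q_scan <- function(x, ...) {
  cat(sprintf("<q_scan> q* = %.3f, r = %.3f, p = %.3g (n = %d)\n",
              x$q_star, x$r, x$p_value, x$n))
  invisible(x)
}
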