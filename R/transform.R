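#' Aggregate a count table to a higher taxonomic level
#'
#' Columns sharing the same lineage prefix down to `level` are summed.
#' Columns whose lineage is unassigned at `level` are pooled per their
#' deepest assigned prefix into a single "unclassified at level" column for
#' that prefix, so per-sample total read counts are conserved exactly.
#' Aggregating at the leaf rank of every column is the identity.
#'
#' @param table a [count_table()].
#' @param level target rank, one of kingdom..species.
#' @return a [count_table()] at `level`, column order by first occurrence.
#' @export
aggregate_to_level <- function(table, level) {
  stopifnot(inherits(table, "count_table"))
  li <- rank_index(level)
  lin <- table$lineages
  # truncate every lineage below `level`; unassigned-at-level columns keep
  # their own (shallower) prefix, which pools them per deepest prefix
  key_lin <- lin
  if (li < 7L) key_lin[, (li + 1L):7L] <- UNCLASSIFIED
  keys <- format_lineage(key_lin)
  first <- !duplicated(keys)
  ord <- keys[first]
  groups <- factor(keys, levels = ord)
  agg <- t(rowsum(t(table$counts), group = groups, reorder = FALSE))
  rownames(agg) <- rownames(table$counts)
  count_table(agg, lineages = key_lin[first, , drop = FALSE],
              site = table$site, level = level)
}

#' Abundance matrices
#'
#' An `abundance_matrix` is the regression-ready form of a count table:
#' each row is a sample's relative-abundance profile (read counts divided
#' by the sample's total reads s_i), optionally paired with the dependent
#' ADD vector `y`. Joint ear+nose matrices concatenate the two per-site
#' blocks, each block normalized independently, so joint rows sum to 2.
#'
#' @name abundance_matrix
#' @seealso [normalize_rows()], [build_joint()], [curate_features()]
NULL

new_abundance_matrix <- function(X, y = NULL, feature_labels = colnames(X),
                                 level, site, curated = FALSE,
                                 row_sums = NULL, cadaver = NULL) {
  colnames(X) <- feature_labels
  structure(list(X = X, y = y, feature_labels = feature_labels,
                 level = level, site = site, curated = curated,
                 row_sums_kept = row_sums, cadaver = cadaver),
            class = "abundance_matrix")
}

#' Row-normalize a count table to relative abundances
#'
#' Divides every row by its total read count s_i = sum_j x_ij. There is no
#' column-based (feature) normalization. A zero-sum row is a hard error
#' naming the offending sample: empty swabs must be dropped explicitly
#' upstream, never silently.
#'
#' @param table a [count_table()].
#' @return an [abundance_matrix] (without `y`); `row_sums_kept` retains
#'   the s_i.
#' @export
normalize_rows <- function(table) {
  stopifnot(inherits(table, "count_table"))
  s <- rowSums(table$counts)
  if (any(s <= 0)) {
    stop("sample(s) with zero total reads: ",
         paste(rownames(table$counts)[s <= 0], collapse = ", "),
         "; drop them upstream before normalization", call. = FALSE)
  }
  X <- table$counts / s
  labels <- paste(table$site, colnames(table$counts), sep = "|")
  new_abundance_matrix(X, feature_labels = labels, level = table$level,
                       site = table$site, row_sums = s)
}

#' Attach the dependent ADD vector and cadaver labels from metadata
#'
#' @param am an [abundance_matrix].
#' @param metadata data frame with columns `sample_id`, `cadaver_id`, `add`.
#' @return the matrix with `y` (ADD, degree days) and `cadaver` filled in.
#' @export
attach_metadata <- function(am, metadata) {
  stopifnot(inherits(am, "abundance_matrix"))
  idx <- match(rownames(am$X), metadata$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(rownames(am$X)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  am$y <- as.numeric(metadata$add[idx])
  if (any(am$y < 0)) stop("negative ADD in metadata", call. = FALSE)
  am$cadaver <- as.character(metadata$cadaver_id[idx])
  am
}

#' Build the joint ear+nose abundance matrix
#'
#' Rows are restricted to swab events present in both sites: the same
#' cadaver sampled at the same time. Columns are the ear feature block
#' followed by the nose block, labels carrying their site tags, so an
#' organism seen at both sites occupies two columns. Each site block keeps
#' its own within-site normalization (each swab is its own sequencing
#' sample), hence joint rows sum to 2.
#'
#' @param ear,nose [abundance_matrix] objects at the same level and
#'   curation status, with `y` and `cadaver` attached (see
#'   [attach_metadata()]).
#' @param metadata data frame with `sample_id`, `cadaver_id`, `add` used to
#'   match swab events across sites; events are matched on
#'   (cadaver_id, add). ADD must agree between the two site records of a
#'   matched event.
#' @return a joint [abundance_matrix]; zero rows if no events match.
#' @export
build_joint <- function(ear, nose, metadata) {
  stopifnot(inherits(ear, "abundance_matrix"),
            inherits(nose, "abundance_matrix"))
  if (!identical(ear$level, nose$level) ||
      !identical(ear$curated, nose$curated)) {
    stop("ear and nose matrices must share level and curation status",
         call. = FALSE)
  }
  key_of <- function(am) {
    idx <- match(rownames(am$X), metadata$sample_id)
    if (anyNA(idx)) {
      stop("samples missing from metadata: ",
           paste(rownames(am$X)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tp <- if ("timepoint" %in% names(metadata)) metadata$timepoint[idx]
          else metadata$add[idx]
    list(key = paste(metadata$cadaver_id[idx], tp, sep = "@"),
         add = as.numeric(metadata$add[idx]),
         cadaver = as.character(metadata$cadaver_id[idx]))
  }
  ke <- key_of(ear); kn <- key_of(nose)
  common <- intersect(ke$key, kn$key)
  ie <- match(common, ke$key); in_ <- match(common, kn$key)
  if (length(common) > 0 &&
      any(abs(ke$add[ie] - kn$add[in_]) > 1e-9)) {
    stop("conflicting ADD between ear and nose records of a matched event",
         call. = FALSE)
  }
  X <- cbind(ear$X[ie, , drop = FALSE], nose$X[in_, , drop = FALSE])
  rownames(X) <- common
  new_abundance_matrix(
    X, y = ke$add[ie],
    feature_labels = c(ear$feature_labels, nose$feature_labels),
    level = ear$level, site = "joint", curated = ear$curated,
    row_sums = cbind(ear = ear$row_sums_kept[ie],
                     nose = nose$row_sums_kept[in_]),
    cadaver = ke$cadaver[ie])
}

#' Programmatic surrogate for manual feature curation
#'
#' The original pruning of taxa was a manual visual inspection of per-taxon
#' abundance-versus-ADD plots, judged on the strength of the correlation
#' with ADD and its coherence across cadavers. This function is an
#' explicitly programmatic surrogate for that step, not a reconstruction of
#' it: a column is kept iff the absolute Pearson correlation of the column
#' with `y` over all rows reaches `min_abs_r`, and the per-cadaver
#' correlations share a single sign in at least `min_agreeing_cadavers`
#' cadavers (cadavers with fewer than 3 samples are skipped).
#'
#' @param am an [abundance_matrix] with `y` attached.
#' @param cadaver_ids per-row cadaver labels; defaults to `am$cadaver`.
#' @param min_abs_r correlation threshold in `[0, 1]` (default 0.3).
#' @param min_agreeing_cadavers required number of sign-agreeing cadavers
#'   (default 3).
#' @return the matrix restricted to the kept columns, tagged
#'   `curated = TRUE`. An empty result is legal.
#' @export
curate_features <- function(am, cadaver_ids = am$cadaver, min_abs_r = 0.3,
                            min_agreeing_cadavers = 3) {
  stopifnot(inherits(am, "abundance_matrix"), !is.null(am$y))
  if (is.null(cadaver_ids)) stop("cadaver ids required for curation", call. = FALSE)
  if (min_abs_r < 0 || min_abs_r > 1) stop("min_abs_r must be in [0,1]", call. = FALSE)
  if (length(unique(cadaver_ids)) < 2) {
    stop("curation needs at least 2 distinct cadavers", call. = FALSE)
  }
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  overall <- apply(am$X, 2, safe_cor, y = am$y)
  eligible <- names(which(table(cadaver_ids) >= 3))
  per_cad <- matrix(0, nrow = ncol(am$X), ncol = length(eligible))
  for (ci in seq_along(eligible)) {
    rows <- cadaver_ids == eligible[ci]
    per_cad[, ci] <- apply(am$X[rows, , drop = FALSE], 2, safe_cor,
                           y = am$y[rows])
  }
  n_pos <- rowSums(per_cad > 0)
  n_neg <- rowSums(per_cad < 0)
  agree <- pmax(n_pos, n_neg)
  keep <- abs(overall) >= min_abs_r & agree >= min_agreeing_cadavers
  out <- new_abundance_matrix(
    am$X[, keep, drop = FALSE], y = am$y,
    feature_labels = am$feature_labels[keep], level = am$level,
    site = am$site, curated = TRUE, row_sums = am$row_sums_kept,
    cadaver = am$cadaver)
  out
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> site=", x$site, " level=", x$level,
      if (x$curated) " (curated)", ": ",
      nrow(x$X), " samples x ", ncol(x$X), " features",
      if (!is.null(x$y)) paste0("; ADD range [",
                                paste(signif(range(x$y), 4), collapse = ", "),
                                "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$X)

#' Identify a dataset variant
#'
#' Dataset variants are identified as `LEVEL_CURATION_SITE`, e.g.
#' `GENUS_NONCURATED_JOINT`.
#'
#' @param level rank name.
#' @param curated logical.
#' @param site `"ear"`, `"nose"` or `"joint"`.
#' @return the id string.
#' @export
dataset_id <- function(level, curated, site) {
  rank_index(level)
  paste(toupper(level), if (curated) "CURATED" else "NONCURATED",
        toupper(site), sep = "_")
}
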