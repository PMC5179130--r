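#' Assemble one dataset variant
#'
#' Builds the regression-ready abundance matrix for a dataset variant
#' (taxonomic level x curation x site) from per-site count tables and
#' metadata: aggregate each site to the level, row-normalize, attach ADD
#' and cadaver labels, optionally curate per site, and for the joint
#' variant concatenate the matched ear and nose blocks.
#'
#' @param ear_table,nose_table [count_table()]s (species level).
#' @param metadata metadata data frame (`sample_id`, `cadaver_id`,
#'   `site`, `add`, optionally `timepoint`).
#' @param level taxonomic rank.
#' @param site `"ear"`, `"nose"` or `"joint"`.
#' @param curated apply the programmatic curation surrogate per site.
#' @param min_abs_r,min_agreeing_cadavers curation thresholds, see
#'   [curate_features()].
#' @return an [abundance_matrix] with `y` attached.
#' @export
build_dataset_matrix <- function(ear_table, nose_table, metadata, level,
                                 site = c("joint", "ear", "nose"),
                                 curated = FALSE, min_abs_r = 0.3,
                                 min_agreeing_cadavers = 3) {
  site <- match.arg(site)
  one_site <- function(tab) {
    am <- attach_metadata(normalize_rows(aggregate_to_level(tab, level)),
                          metadata)
    if (curated) {
      am <- curate_features(am, min_abs_r = min_abs_r,
                            min_agreeing_cadavers = min_agreeing_cadavers)
    }
    am
  }
  if (site == "ear") return(one_site(ear_table))
  if (site == "nose") return(one_site(nose_table))
  build_joint(one_site(ear_table), one_site(nose_table), metadata)
}

#' Dataset dimension summary
#'
#' One row per dataset variant: sample count, organism (column) count,
#' and the natural logarithm of the column count -- the model-complexity
#' axis used when relating error to dataset dimensionality.
#'
#' @param matrices named list of [abundance_matrix] objects (names are
#'   dataset ids).
#' @return data frame with `dataset`, `n_samples`, `n_organisms`,
#'   `logarithm`.
#' @export
dataset_summary <- function(matrices) {
  n_org <- vapply(matrices, function(m) ncol(m$X), integer(1))
  data.frame(dataset = names(matrices),
             n_samples = vapply(matrices, function(m) nrow(m$X), integer(1)),
             n_organisms = n_org,
             logarithm = ifelse(n_org > 0, log(n_org), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Model-complexity axis of a dataset
#'
#' The natural logarithm of the feature (organism) count, used as the
#' complexity coordinate in bias-variance sweeps across dataset variants.
#'
#' @param n_features positive feature counts.
#' @return `log(n_features)`.
#' @export
feature_complexity <- function(n_features) {
  if (any(n_features <= 0)) stop("feature counts must be positive", call. = FALSE)
  log(n_features)
}

#' Pipeline configuration
#'
#' @param datasets data frame with columns `level`, `curated`, `site`
#'   defining the variants to analyze; the default is the 13 joint
#'   variants (kingdom has no curated variant).
#' @param q_grid diversity orders for the q-scan.
#' @param hypergrid hyperparameter grids (see [default_hypergrid()]).
#' @param families estimator families entered in the model census.
#' @param seed global seed driving split and folds.
#' @param folds cross-validation folds (default 10).
#' @param top_n leaderboard depth.
#' @param ranking_methods feature-ranking methods to run.
#' @param min_abs_r,min_agreeing_cadavers curation surrogate thresholds.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(datasets = default_dataset_specs(),
                            q_grid = seq(0, 5, length.out = 200),
                            hypergrid = default_hypergrid(),
                            families = c("dummy", "knr", "ridge", "lasso",
                                         "elastic_net"),
                            seed = 1, folds = 10, top_n = 10,
                            ranking_methods = c("f_value", "tree",
                                                "mutual_information"),
                            min_abs_r = 0.3, min_agreeing_cadavers = 3) {
  structure(list(datasets = datasets, q_grid = q_grid,
                 hypergrid = hypergrid, families = families, seed = seed,
                 folds = folds, top_n = top_n,
                 ranking_methods = ranking_methods, min_abs_r = min_abs_r,
                 min_agreeing_cadavers = min_agreeing_cadavers),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_dataset_specs <- function() {
  specs <- expand.grid(level = TAXON_RANKS, curated = c(FALSE, TRUE),
                       site = "joint", stringsAsFactors = FALSE)
  specs[!(specs$level == "kingdom" & specs$curated), , drop = FALSE]
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `q_grid` may
#' be given as `q_min`/`q_max`/`q_points`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$datasets)) {
    args$datasets <- do.call(rbind, lapply(y$datasets, function(d) {
      data.frame(level = d$level, curated = isTRUE(d$curated),
                 site = if (is.null(d$site)) "joint" else d$site,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(y$q_min)) {
    args$q_grid <- seq(y$q_min, y$q_max,
                       length.out = if (is.null(y$q_points)) 200 else y$q_points)
  }
  for (k in c("seed", "folds", "top_n", "families", "ranking_methods",
              "min_abs_r", "min_agreeing_cadavers")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' For every configured dataset variant: builds the abundance matrix,
#' scans diversity order q against ADD, grid-searches every estimator
#' family under the shared 80/20 split and k-fold partition, and collects
#' leaderboards ranked by training (cross-validation) error and by test
#' error, the training-versus-test error census with its Pearson
#' correlation, an error-versus-log-dimensionality table, feature-ranking
#' tables with cross-method consensus on the first configured dataset,
#' and prediction-versus-truth pairs for the champion models. All outputs
#' are plain data frames; `out_dir`, when given, additionally writes them
#' as TSV with a provenance header (seed, config hash, package version).
#'
#' @param ear_table,nose_table [count_table()]s.
#' @param metadata metadata data frame.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return (invisibly) list with `summary`, `qscan`, `leaderboard_train`,
#'   `leaderboard_test`, `census`, `census_correlation`, `complexity`,
#'   `ranking`, `consensus`, `champion_predictions`, `matrices`.
#' @export
run_pipeline <- function(ear_table, nose_table, metadata,
                         config = pipeline_config(), out_dir = NULL) {
  specs <- config$datasets
  ids <- mapply(dataset_id, specs$level, specs$curated, specs$site)
  matrices <- list()
  qscan_rows <- list()
  entries <- list()
  for (i in seq_len(nrow(specs))) {
    id <- ids[i]
    am <- build_dataset_matrix(ear_table, nose_table, metadata,
                               level = specs$level[i], site = specs$site[i],
                               curated = specs$curated[i],
                               min_abs_r = config$min_abs_r,
                               min_agreeing_cadavers = config$min_agreeing_cadavers)
    matrices[[id]] <- am
    if (ncol(am$X) > 0) {
      qs <- tryCatch(q_scan(am, q_grid = config$q_grid),
                     error = function(e) NULL)
      if (!is.null(qs)) {
        qscan_rows[[id]] <- data.frame(dataset = id, q_star = qs$q_star,
                                       r = qs$r, p = qs$p_value, n = qs$n,
                                       stringsAsFactors = FALSE)
      }
    }
    entries[[id]] <- census_entries(am, id, config)
  }
  census <- do.call(rbind, c(entries, list(make.row.names = FALSE)))
  # undefined when the census errors are constant (degenerate datasets)
  cc <- tryCatch(pearson_r_p(census$training_error, census$test_error),
                 error = function(e) list(r = NA_real_, p_value = NA_real_,
                                          n = nrow(census)))
  summary_df <- dataset_summary(matrices)
  complexity <- merge(summary_df[, c("dataset", "n_organisms", "logarithm")],
                      census, by = "dataset")
  ranking <- list(); consensus <- NULL
  rank_id <- ids[1]
  rank_am <- matrices[[rank_id]]
  if (ncol(rank_am$X) >= 2) {
    ranking <- rank_features(rank_am, methods = config$ranking_methods,
                             seed = config$seed)
    consensus <- top_k_consensus(ranking, k = min(5, ncol(rank_am$X)))
  }
  champs <- champion_predictions(matrices, census, config)
  out <- list(summary = summary_df,
              qscan = do.call(rbind, c(qscan_rows, list(make.row.names = FALSE))),
              leaderboard_train = build_leaderboard(census, "training_error",
                                                    config$top_n),
              leaderboard_test = build_leaderboard(census, "test_error",
                                                   config$top_n),
              census = census, census_correlation = cc,
              complexity = complexity, ranking = ranking,
              consensus = consensus, champion_predictions = champs,
              matrices = matrices, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

# Grid-search every family on one dataset under the shared split/folds.
census_entries <- function(am, id, config) {
  X <- am$X; y <- am$y
  if (ncol(X) == 0) return(NULL)
  sp <- make_split(nrow(X), seed = config$seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
  folds <- kfold_partition(seq_len(nrow(Xtr)),
                           folds = min(config$folds, nrow(Xtr)),
                           seed = config$seed)
  ref <- mean(y)
  rows <- lapply(config$families, function(fam) {
    gs <- grid_search(fam, config$hypergrid[[fam]], Xtr, ytr, folds)
    evaluate_model(gs$spec, Xtr, ytr, Xte, yte, ref, dataset = id,
                   training_error = gs$cv$mean_error)
  })
  do.call(rbind, rows)
}

rank_features <- function(am, methods, seed) {
  out <- list()
  if ("f_value" %in% methods) out$f_value <- f_value_scores(am)
  if ("tree" %in% methods) out$tree <- tree_importance_scores(am, seed = seed)
  if ("mutual_information" %in% methods) {
    out$mutual_information <- mutual_information_scores(am, seed = seed)
  }
  out
}

# Prediction-vs-truth pairs on the test set for the champion model under
# each ranking (lowest training CV error; lowest test error).
champion_predictions <- function(matrices, census, config) {
  one <- function(rank_by) {
    row <- census[order(census[[rank_by]])[1], ]
    am <- matrices[[row$dataset]]
    sp <- make_split(nrow(am$X), seed = config$seed)
    spec <- model_spec_from_json(row$hyperparameters)
    fit <- suppressWarnings(fit_model(spec, am$X[sp$train, , drop = FALSE],
                                      am$y[sp$train]))
    data.frame(ranked_by = rank_by, dataset = row$dataset,
               regressor = row$regressor,
               true_add = am$y[sp$test],
               predicted_add = predict(fit, am$X[sp$test, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }
  rbind(one("training_error"), one("test_error"))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("seed=", out$config$seed),
           paste0("config_hash=", content_hash(out$config)),
           paste0("necroclock_version=",
                  as.character(utils::packageVersion("necroclock"))))
  wr <- function(df, name) {
    con <- file(file.path(out_dir, name), "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste0("# ", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(out$summary, "dataset_summary.tsv")
  if (!is.null(out$qscan)) wr(out$qscan, "diversity_qscan.tsv")
  write_leaderboard(out$leaderboard_train,
                    file.path(out_dir, "leaderboard_by_training_error.tsv"),
                    header_lines = hdr)
  write_leaderboard(out$leaderboard_test,
                    file.path(out_dir, "leaderboard_by_test_error.tsv"),
                    header_lines = hdr)
  wr(out$census[, setdiff(names(out$census), "hyperparameters")],
     "model_census.tsv")
  wr(data.frame(r = out$census_correlation$r,
                p = out$census_correlation$p_value,
                n = out$census_correlation$n), "census_correlation.tsv")
  wr(out$complexity[, c("dataset", "n_organisms", "logarithm", "regressor",
                        "training_error", "test_error")],
     "error_vs_complexity.tsv")
  if (!is.null(out$consensus)) wr(out$consensus, "feature_consensus.tsv")
  wr(out$champion_predictions, "champion_predictions.tsv")
  invisible(out_dir)
}
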