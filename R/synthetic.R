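#' Synthetic cadaver-structured succession data
#'
#' Generates skin-microbiome succession datasets with known ground truth:
#' repeated ear and nose swabs from a small cohort of cadavers across
#' 0-500 accumulated degree days, with taxa following smooth
#' abundance-versus-ADD trajectories modulated by per-cadaver random
#' effects, observed through Dirichlet-multinomial sequencing noise. The
#' ear and nose receive distinct informative-taxon sets, so joint
#' ear+nose matrices carry more signal than either site alone -- the
#' statistical structure the downstream analysis assumes.
#'
#' @name synthetic_data
NULL

#' Generate a seven-rank taxonomy
#'
#' Builds `n_species` lineages forming a proper rank tree. `branching`
#' gives the expected children-per-parent ratio at each step up from
#' species (species->genus, genus->family, ..., phylum->kingdom); the
#' count at each rank is `ceiling(child_count / ratio)` and children are
#' assigned to parents contiguously, so the counts are exact and the tree
#' is deterministic.
#'
#' @param n_species leaf count.
#' @param branching numeric vector of 6 ratios (recycled from a scalar).
#' @param seed accepted for interface symmetry; the topology is already
#'   deterministic.
#' @return lineage character matrix (`n_species` x 7) with rank columns.
#' @export
generate_taxonomy <- function(n_species, branching = 2, seed = 1) {
  branching <- rep_len(branching, 6)
  if (any(branching < 1)) stop("branching ratios must be >= 1", call. = FALSE)
  counts <- integer(7)                      # species .. kingdom
  counts[1] <- n_species
  for (i in 1:6) counts[i + 1] <- max(1L, ceiling(counts[i] / branching[i]))
  if (any(diff(counts) > 0)) {
    stop("impossible branching: a parent rank would outnumber its children",
         call. = FALSE)
  }
  ranks_desc <- rev(TAXON_RANKS)            # species first
  name_at <- function(rank, i) sprintf("%s%03d", toupper(substr(rank, 1, 2)), i)
  idx <- vector("list", 7)
  idx[[1]] <- seq_len(n_species)
  for (i in 1:6) {
    idx[[i + 1]] <- ceiling(idx[[i]] * counts[i + 1] / counts[i])
  }
  lin <- matrix(UNCLASSIFIED, nrow = n_species, ncol = 7,
                dimnames = list(NULL, TAXON_RANKS))
  for (i in 1:7) {
    rank <- ranks_desc[i]
    lin[, rank] <- name_at(rank, idx[[i]])
  }
  lin
}

#' Taxon abundance trajectories
#'
#' The expected (pre-normalization) abundance of a taxon as a function of
#' ADD, in one of four shapes: `bloom` (Gaussian pulse around
#' `peak_add`), `growth` / `decay` (logistic rise / fall centered at
#' `peak_add` with slope scale `width`), or `flat` (constant baseline).
#' Per-cadaver multiplicative effects scale the amplitude, reproducing
#' the between-cadaver spread seen in real succession curves.
#'
#' @param shape one of `"bloom"`, `"decay"`, `"growth"`, `"flat"`.
#' @param peak_add trajectory center, degree days.
#' @param width pulse width / logistic scale, degree days (> 0).
#' @param amplitude trajectory amplitude (>= 0), relative-abundance scale.
#' @param baseline constant floor (>= 0).
#' @param cadaver_effects named vector of per-cadaver multipliers on the
#'   amplitude.
#' @return object of class `taxon_trajectory`.
#' @export
taxon_trajectory <- function(shape = c("bloom", "decay", "growth", "flat"),
                             peak_add = 250, width = 100, amplitude = 1,
                             baseline = 0, cadaver_effects = NULL) {
  shape <- match.arg(shape)
  if (width <= 0 || amplitude < 0 || baseline < 0) {
    stop("need width > 0, amplitude >= 0, baseline >= 0", call. = FALSE)
  }
  structure(list(shape = shape, peak_add = peak_add, width = width,
                 amplitude = amplitude, baseline = baseline,
                 cadaver_effects = cadaver_effects),
            class = "taxon_trajectory")
}

#' @rdname taxon_trajectory
#' @param traj a `taxon_trajectory`.
#' @param add ADD value(s), degree days (>= 0).
#' @param cadaver optional cadaver id selecting its amplitude effect
#'   (effect 1 when absent).
#' @return expected relative abundance (pre-normalization), always >= 0.
#' @export
trajectory_value <- function(traj, add, cadaver = NULL) {
  ce <- 1
  if (!is.null(cadaver) && !is.null(traj$cadaver_effects)) {
    ce <- traj$cadaver_effects[[as.character(cadaver)]]
  }
  a <- traj$amplitude * ce
  switch(traj$shape,
    flat = rep(traj$baseline, length(add)),
    bloom = traj$baseline + a * exp(-(add - traj$peak_add)^2 /
                                      (2 * traj$width^2)),
    growth = traj$baseline + a * stats::plogis((add - traj$peak_add) /
                                                 traj$width),
    decay = traj$baseline + a * stats::plogis(-(add - traj$peak_add) /
                                                traj$width))
}

#' Configuration for the synthetic generator
#'
#' Defaults emulate the study design the pipeline targets: 4 cadavers
#' swabbed repeatedly at both sites, about 17 matched swab events each at
#' roughly uniform ADD intervals over 0-500 degree days, a taxonomy of
#' 300 species aggregating to roughly 120 genera / 50 families / 22
#' orders / 12 classes / 6 phyla, 15% of species informative (distinct
#' sets per site), sequencing depth 50000 reads per swab, and
#' Dirichlet-multinomial overdispersion with concentration 200.
#'
#' @param n_cadavers cohort size.
#' @param samples_per_cadaver matched ear+nose swab events per cadaver.
#' @param add_range ADD span, degree days.
#' @param n_species leaf taxa.
#' @param branching taxonomy branching ratios (see [generate_taxonomy()]).
#' @param informative_fraction share of species with ADD-dependent
#'   trajectories, in `[0, 1]`.
#' @param depth reads per swab.
#' @param concentration Dirichlet concentration (`Inf` = plain
#'   multinomial).
#' @param cadaver_sigma sd of the lognormal per-cadaver amplitude effects.
#' @param planted_signal `"none"` for the standard mixture of bloom /
#'   growth / decay trajectories; `"richness_decline"` plants taxa that
#'   drop out as ADD accrues (sample richness falls with ADD);
#'   `"evenness_decline"` plants rising dominants at constant richness.
#' @param seed integer; identical config + seed gives identical data.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cadavers = 4, samples_per_cadaver = 17,
                             add_range = c(0, 500), n_species = 300,
                             branching = c(2.5, 2.4, 2.3, 1.8, 2, 3),
                             informative_fraction = 0.15, depth = 5e4,
                             concentration = 200, cadaver_sigma = 0.3,
                             planted_signal = c("none", "richness_decline",
                                                "evenness_decline"),
                             seed = 1) {
  planted_signal <- match.arg(planted_signal)
  if (informative_fraction < 0 || informative_fraction > 1) {
    stop("informative_fraction must be in [0,1]", call. = FALSE)
  }
  if (n_cadavers < 1 || samples_per_cadaver < 1 || n_species < 1 ||
      depth < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  structure(list(n_cadavers = n_cadavers,
                 samples_per_cadaver = samples_per_cadaver,
                 add_range = add_range, n_species = n_species,
                 branching = branching,
                 informative_fraction = informative_fraction,
                 depth = depth, concentration = concentration,
                 cadaver_sigma = cadaver_sigma,
                 planted_signal = planted_signal, seed = seed),
            class = "synthetic_config")
}

# Draw the per-site trajectory set. Informative species get bloom /
# growth / decay shapes with peaks spread over the ADD range; the rest
# are flat with long-tailed lognormal baselines.
draw_trajectories <- function(config, informative_idx, cadavers) {
  n <- config$n_species
  baselines <- exp(stats::rnorm(n, 0, 1.5))
  mb <- mean(baselines)
  lapply(seq_len(n), function(j) {
    ce <- stats::setNames(
      exp(stats::rnorm(length(cadavers), 0, config$cadaver_sigma)), cadavers)
    if (!(j %in% informative_idx)) {
      # evenness mode keeps an equal-abundance background so that
      # equitability, not baseline spread, carries the planted signal
      bl <- if (config$planted_signal == "evenness_decline") 1
            else baselines[j]
      return(taxon_trajectory("flat", baseline = bl))
    }
    amp <- 10 * mb * exp(stats::rnorm(1, 0, 0.5))
    peak <- stats::runif(1, config$add_range[1], config$add_range[2])
    width <- stats::runif(1, 50, 150)
    if (config$planted_signal == "richness_decline") {
      # taxa vanish as ADD accrues: no floor, staggered logistic decays
      return(taxon_trajectory("decay", peak_add = peak, width = 40,
                              amplitude = amp, baseline = 0,
                              cadaver_effects = ce))
    }
    if (config$planted_signal == "evenness_decline") {
      # rising dominants; generate_dataset additionally churns the
      # background membership per swab (ADD-independent), so richness is
      # noise and the ADD signal lives in equitability alone
      return(taxon_trajectory("growth", peak_add = peak, width = width,
                              amplitude = 6, baseline = 0,
                              cadaver_effects = ce))
    }
    shape <- sample(c("bloom", "growth", "decay"), 1)
    taxon_trajectory(shape, peak_add = peak, width = width, amplitude = amp,
                     baseline = 0.1 * baselines[j], cadaver_effects = ce)
  })
}

dirichlet_multinomial <- function(p, depth, concentration) {
  if (is.finite(concentration)) {
    g <- stats::rgamma(length(p), shape = concentration * p)
    if (sum(g) == 0) g[which.max(p)] <- 1
    p <- g / sum(g)
  }
  drop(stats::rmultinom(1, size = depth, prob = p))
}

#' Generate a full synthetic dataset
#'
#' Produces matched ear and nose count tables, sample metadata with true
#' ADD, and a ground-truth report (informative taxa per site, trajectory
#' parameters, expected compositions). Sampling ADDs are laid out on a
#' jittered uniform grid over the configured range per cadaver. Read
#' counts are Dirichlet-multinomial at the configured depth, so every
#' sample's counts sum to the depth exactly. Identical config and seed
#' give identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with `ear` and `nose` [count_table()]s, `metadata` data
#'   frame (`sample_id`, `cadaver_id`, `site`, `collection_date`, `add`,
#'   `timepoint`), and `ground_truth` (informative indices and labels per
#'   site, trajectories, expected composition matrices).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_inf <- round(config$informative_fraction * config$n_species)
  if (n_inf > 0 && 2 * n_inf > config$n_species) {
    stop("informative_fraction too large for disjoint per-site sets",
         call. = FALSE)
  }
  with_seed(config$seed, {
    lineages <- generate_taxonomy(config$n_species, config$branching)
    cadavers <- sprintf("C%02d", seq_len(config$n_cadavers))
    pool <- sample(config$n_species, 2 * n_inf)
    inf <- list(ear = sort(pool[seq_len(n_inf)]),
                nose = sort(pool[n_inf + seq_len(n_inf)]))
    trajs <- list(ear = draw_trajectories(config, inf$ear, cadavers),
                  nose = draw_trajectories(config, inf$nose, cadavers))

    nt <- config$samples_per_cadaver
    span <- diff(config$add_range)
    spacing <- span / max(nt - 1, 1)
    add_of <- lapply(cadavers, function(cid) {
      grid <- seq(config$add_range[1], config$add_range[2], length.out = nt)
      pmin(pmax(grid + stats::runif(nt, -spacing / 4, spacing / 4),
                config$add_range[1]), config$add_range[2])
    })
    names(add_of) <- cadavers

    meta <- list(); tables <- list()
    expected <- list()
    for (site in c("ear", "nose")) {
      counts <- NULL; ids <- character(); exp_rows <- NULL
      for (cid in cadavers) {
        for (t in seq_len(nt)) {
          add <- add_of[[cid]][t]
          v <- vapply(trajs[[site]], trajectory_value, numeric(1),
                      add = add, cadaver = cid)
          if (config$planted_signal == "evenness_decline") {
            # random background membership per swab: richness varies
            # independently of ADD while the dominants carry the signal
            bg <- setdiff(seq_along(v), inf[[site]])
            drop_n <- floor(length(bg) * stats::runif(1, 0, 0.6))
            v[sample(bg, drop_n)] <- 0
          }
          p <- v / sum(v)
          counts <- rbind(counts,
                          dirichlet_multinomial(p, config$depth,
                                                config$concentration))
          exp_rows <- rbind(exp_rows, p)
          sid <- sprintf("%s_T%02d_%s", cid, t, site)
          ids <- c(ids, sid)
          meta[[length(meta) + 1]] <- data.frame(
            sample_id = sid, cadaver_id = cid, site = site,
            collection_date = format(as.Date("2015-06-01") + 2 * (t - 1)),
            add = add, timepoint = t, stringsAsFactors = FALSE)
        }
      }
      rownames(counts) <- ids
      rownames(exp_rows) <- ids
      tables[[site]] <- count_table(counts, lineages = lineages, site = site)
      expected[[site]] <- exp_rows
    }
    metadata <- do.call(rbind, meta)
    species_labels <- format_lineage(lineages)
    list(ear = tables$ear, nose = tables$nose, metadata = metadata,
         ground_truth = list(
           informative = inf,
           informative_labels = list(ear = species_labels[inf$ear],
                                     nose = species_labels[inf$nose]),
           trajectories = trajs,
           expected_composition = expected,
           add = add_of),
         config = config)
  })
}

#' Write a synthetic dataset to disk
#'
#' Standard formats: per-site counts TSV (see [write_count_table()]),
#' metadata CSV, and a ground-truth JSON listing the informative taxa.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$ear, file.path(dir, "counts_ear.tsv"))
  write_count_table(dataset$nose, file.path(dir, "counts_nose.tsv"))
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(informative_labels = dataset$ground_truth$informative_labels,
         seed = dataset$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
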