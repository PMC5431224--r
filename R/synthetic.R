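#' @name synthetic-data
#' @title Synthetic toxicogenomics datasets with planted truth
#'
#' @description
#' Generates datasets that emulate the structure of a large public
#' toxicogenomics archive: a panel of compounds, four dose levels
#' (Control/Low/Middle/High), a time course from hours to weeks, ~3
#' replicates per condition, and matched vehicle-control groups per
#' compound and time. Intensities are log-normal: the log2 intensity of a
#' probe in a sample is a probe baseline plus a planted condition effect
#' plus Gaussian noise (a heavier-tailed Student-t option exists for
#' robustness experiments). The generator returns the planted truth -
#' differentially expressed blocks, cluster labels, the consistently
#' halved probe set, and the planted down-regulating compound - so every
#' downstream stage can be tested for recovery without any download.
NULL

#' Simulation configuration
#'
#' Defaults mirror a repeat-dose liver design: 10 compounds x 4 dose
#' levels x 4 time points (4/8/15/29 days) x 3 replicates on a 1000-probe
#' panel, baseline log2 intensity ~ N(7, 1), residual noise sd 0.1 on the
#' log2 scale. The default effect model plants, for the first compound at
#' the Middle dose, three 60-probe blocks with distinct time profiles
#' (early up +2, late up +2, and always down <= -1.5) - so the same
#' dataset exercises fold-change filtering, 3-cluster recovery, consistent
#' down-regulation extraction and compound ranking.
#'
#' @param n_probes number of probes.
#' @param compounds character vector of compound names.
#' @param dose_levels dose levels; must contain `"Control"`.
#' @param time_points character vector of exposure times.
#' @param replicates samples per (compound, dose, time); >= 2.
#' @param organ,species,platform,test_type constant metadata fields.
#' @param baseline_mean,baseline_sd probe baseline log2-intensity model.
#' @param noise_sd residual sd on the log2 scale.
#' @param noise `"gaussian"` (default) or `"t"` (df 3, scaled to
#'   `noise_sd`) for heavier tails.
#' @param effects planted effect model: list of entries
#'   `list(probes, compound, dose_levels, time_points, log2fc)`; `NULL`
#'   uses the default model above.
#' @param seed integer seed (mandatory: every dataset is reproducible).
#' @return An object of class `tox_sim_config`.
#' @export
sim_config <- function(n_probes = 1000L,
                       compounds = sprintf("CPD%02d", 1:10),
                       dose_levels = c("Control", "Low", "Middle", "High"),
                       time_points = c("4 day", "8 day", "15 day",
                                       "29 day"),
                       replicates = 3L,
                       organ = "liver", species = "rat",
                       platform = "Rat230_2", test_type = "in_vivo",
                       baseline_mean = 7, baseline_sd = 1,
                       noise_sd = 0.1, noise = c("gaussian", "t"),
                       effects = NULL, seed) {
  noise <- match.arg(noise)
  check_that(!missing(seed), "`seed` is mandatory for reproducibility")
  check_that(n_probes >= 1L, "`n_probes` must be positive")
  check_that("Control" %in% dose_levels,
             "`dose_levels` must contain \"Control\"")
  check_that(replicates >= 2L, "`replicates` must be >= 2")
  check_that(noise_sd >= 0, "`noise_sd` must be non-negative")
  probes <- sprintf("P%05d", seq_len(n_probes))
  if (is.null(effects)) {
    effects <- default_effects(probes, compounds, time_points)
  }
  for (e in effects) {
    check_that(all(e$probes %in% probes) &&
               all(e$compound %in% compounds) &&
               all(e$dose_levels %in% setdiff(dose_levels, "Control")) &&
               all(e$time_points %in% time_points) &&
               is.numeric(e$log2fc),
               "invalid effect entry (unknown probe/compound/dose/time)")
  }
  structure(list(n_probes = as.integer(n_probes), probes = probes,
                 compounds = compounds, dose_levels = dose_levels,
                 time_points = time_points,
                 replicates = as.integer(replicates),
                 organ = organ, species = species, platform = platform,
                 test_type = test_type,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, noise = noise,
                 effects = effects, seed = as.integer(seed)),
            class = "tox_sim_config")
}

# three 60-probe blocks on the first compound, Middle dose:
#   block A: +2 early (first two time points)      -> cluster 1
#   block B: +2 late (last two time points)        -> cluster 2
#   block C: -2 / -1.5 alternating, down always    -> cluster 3, the
#            consistently halved set (fold <= 0.5 at every time point);
#            the profile varies over time so correlation distance is
#            well defined
default_effects <- function(probes, compounds, time_points) {
  check_that(length(probes) >= 180L,
             "default effect model needs >= 180 probes")
  check_that(length(time_points) >= 4L,
             "default effect model needs >= 4 time points")
  cpd <- compounds[1L]
  blockA <- probes[1:60]; blockB <- probes[61:120]
  blockC <- probes[121:180]
  odd <- time_points[c(1L, 3L)]; even <- time_points[c(2L, 4L)]
  list(
    list(probes = blockA, compound = cpd, dose_levels = "Middle",
         time_points = time_points[1:2], log2fc = 2),
    list(probes = blockB, compound = cpd, dose_levels = "Middle",
         time_points = time_points[3:4], log2fc = 2),
    list(probes = blockC, compound = cpd, dose_levels = "Middle",
         time_points = odd, log2fc = -2),
    list(probes = blockC, compound = cpd, dose_levels = "Middle",
         time_points = even, log2fc = -1.5))
}

# planted effect per probe for one (compound, dose, time) condition
effect_vector <- function(config, compound, dose, time) {
  eff <- numeric(config$n_probes)
  names(eff) <- config$probes
  for (e in config$effects) {
    if (compound %in% e$compound && dose %in% e$dose_levels &&
        time %in% e$time_points) {
      eff[e$probes] <- eff[e$probes] + e$log2fc
    }
  }
  eff
}

#' Generate a synthetic dataset with planted truth
#'
#' Draws probe baselines, then one noise value per cell, in a fixed order
#' under the configured seed, so identical configurations produce
#' identical datasets (and identical files via [write_dataset()]).
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [tox_dataset()]) and `truth`, a list
#'   holding the expanded planted `effects` table, `deg_sets` (per
#'   condition key `compound/dose/time`, the probes with planted
#'   |log2 effect| >= 1.5), `cluster_blocks` (the three planted profile
#'   blocks with the scope they apply to and a recommended cutoff),
#'   `consistent_down` (probes planted at fold <= 0.5 at all time
#'   points), and `ranked_compound` (the planted down-regulator).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "tox_sim_config"))
  meta <- build_meta(config)
  n_s <- nrow(meta)
  with_seed(config$seed, {
    baseline <- stats::rnorm(config$n_probes, config$baseline_mean,
                             config$baseline_sd)
    noise <- if (config$noise == "gaussian") {
      stats::rnorm(config$n_probes * n_s, 0, config$noise_sd)
    } else {
      stats::rt(config$n_probes * n_s, df = 3) / sqrt(3) * config$noise_sd
    }
    noise <- matrix(noise, nrow = config$n_probes, ncol = n_s)
    log2m <- baseline + noise
    for (j in seq_len(n_s)) {
      if (meta$dose_level[j] == "Control") next
      eff <- effect_vector(config, meta$compound[j], meta$dose_level[j],
                           meta$exposure_time[j])
      log2m[, j] <- log2m[, j] + eff
    }
    intensities <- 2^log2m
    dimnames(intensities) <- list(config$probes, meta$sample_id)
    dataset <- tox_dataset(intensities, meta)
    list(dataset = dataset, truth = build_truth(config))
  })
}

build_meta <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      exposure_time = config$time_points,
                      dose_level = config$dose_levels,
                      compound = config$compounds,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("compound", "dose_level", "exposure_time", "replicate")]
  time_tag <- gsub("[^A-Za-z0-9]", "", grid$exposure_time)
  sample_id <- sprintf("%s_%s_%s_r%d", grid$compound, grid$dose_level,
                       time_tag, grid$replicate)
  data.frame(sample_id = sample_id, compound = grid$compound,
             dose_level = grid$dose_level,
             exposure_time = grid$exposure_time,
             organ = config$organ, species = config$species,
             platform = config$platform, test_type = config$test_type,
             control_group = paste(grid$compound, config$organ,
                                   grid$exposure_time, sep = "|"),
             stringsAsFactors = FALSE)
}

build_truth <- function(config) {
  expanded <- do.call(rbind, lapply(config$effects, function(e) {
    expand.grid(probe = e$probes, compound = e$compound,
                dose_level = e$dose_levels, time_point = e$time_points,
                log2fc = e$log2fc, stringsAsFactors = FALSE)
  }))
  if (is.null(expanded)) {
    expanded <- data.frame(probe = character(), compound = character(),
                           dose_level = character(),
                           time_point = character(), log2fc = numeric())
  }
  # per-condition planted DEG sets at the conventional |log2FC| >= 1.5
  deg_sets <- list()
  if (nrow(expanded) > 0L) {
    key <- paste(expanded$compound, expanded$dose_level,
                 expanded$time_point, sep = "/")
    agg <- tapply(expanded$log2fc, list(expanded$probe, key), sum)
    deg_sets <- lapply(colnames(agg), function(k) {
      v <- agg[, k]
      rownames(agg)[!is.na(v) & abs(v) >= 1.5]
    })
    names(deg_sets) <- colnames(agg)
  }
  is_default <- config$n_probes >= 180L &&
    length(config$time_points) >= 4L &&
    identical(config$effects, default_effects(config$probes,
                                              config$compounds,
                                              config$time_points))
  cluster_blocks <- NULL; consistent_down <- NULL; ranked <- NULL
  if (is_default) {
    cluster_blocks <- list(
      labels = setNames(rep(1:3, each = 60L), config$probes[1:180]),
      compound = config$compounds[1L], dose_level = "Middle",
      time_points = config$time_points[1:4],
      recommended_cutoff = 1.0)
    consistent_down <- config$probes[121:180]
    ranked <- config$compounds[1L]
  }
  list(effects = expanded, deg_sets = deg_sets,
       cluster_blocks = cluster_blocks,
       consistent_down = consistent_down,
       ranked_compound = ranked)
}

#' Generate a synthetic GMT collection with one planted enriched category
#'
#' One category (`"planted"`) draws `round(overlap_rate * category_size)`
#' of its members from the planted gene set and the rest from the
#' remaining universe; the other categories are uniform draws from the
#' whole universe.
#'
#' @param universe character vector of all gene/probe IDs.
#' @param planted_set character vector, the planted "interesting" genes
#'   (e.g. a truth DEG set).
#' @param n_categories total number of categories (>= 1).
#' @param category_size members per category.
#' @param overlap_rate fraction of the planted category drawn from
#'   `planted_set` (1 means the category is a subset of it).
#' @param seed integer seed.
#' @param name collection name.
#' @return List with `collection` (an [annotation_collection()], category
#'   IDs `"planted"`, `"null01"`, ...) and `truth`
#'   (`list(planted_category, planted_overlap)`).
#' @export
generate_collection <- function(universe, planted_set, n_categories = 50L,
                                category_size = 40L, overlap_rate = 0.9,
                                seed, name = "synthetic_collection") {
  check_that(!missing(seed), "`seed` is mandatory for reproducibility")
  universe <- unique(as.character(universe))
  planted_set <- unique(as.character(planted_set))
  check_that(all(planted_set %in% universe),
             "`planted_set` must be a subset of `universe`")
  check_that(category_size <= length(universe),
             "category size exceeds the universe")
  n_planted <- round(overlap_rate * category_size)
  check_that(n_planted <= length(planted_set),
             "infeasible overlap: %d planted members requested, %d available",
             n_planted, length(planted_set))
  with_seed(seed, {
    planted_members <- c(
      sample(planted_set, n_planted),
      sample(setdiff(universe, planted_set),
             category_size - n_planted))
    cats <- list(planted = list(
      description = "synthetic planted-enrichment category",
      members = planted_members))
    if (n_categories > 1L) {
      for (i in seq_len(n_categories - 1L)) {
        cats[[sprintf("null%02d", i)]] <- list(
          description = "synthetic background category",
          members = sample(universe, category_size))
      }
    }
    list(collection = annotation_collection(name, cats,
                                            feature_type = "other"),
         truth = list(planted_category = "planted",
                      planted_overlap = n_planted))
  })
}
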