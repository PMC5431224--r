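small_config <- function(seed, replicates = 2L, ...) {
  sim_config(n_probes = 200L, compounds = c("CPDA", "CPDB"),
             time_points = c("4 day", "8 day", "15 day", "29 day"),
             replicates = replicates, seed = seed, ...)
}

test_that("config validation catches bad inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, dose_levels = c("Low", "High")),
               "Control")
  expect_error(sim_config(seed = 1, replicates = 1L), ">= 2")
  expect_error(sim_config(seed = 1, n_probes = 200,
                          effects = list(list(probes = "P99999",
                                              compound = "CPD01",
                                              dose_levels = "Middle",
                                              time_points = "4 day",
                                              log2fc = 1))),
               "invalid effect")
})

test_that("zero effects and zero noise give folds of exactly 1", {
  cfg <- small_config(seed = 2, noise_sd = 0, effects = list())
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  groups <- make_groups(ds)
  tab <- build_group_matrix(ds, groups)
  expect_true(all(tab$folds == 1))
  expect_true(all(tab$values == 0))
})

test_that("planted effect is recovered within the noise-model tolerance", {
  # one +2 block of 500 probes at noise sd 0.1, n = 3 + 3: the group
  # value sd is ~ 0.1 * sqrt(1/3 + 1/3) = 0.082, so +/-0.2 is ~2.45
  # sigma (nominal coverage 98.6%); assert >= 96% to absorb binomial
  # sampling noise (~4 sigma at n = 500)
  probes <- sprintf("P%05d", 1:600)
  cfg <- sim_config(n_probes = 600L, compounds = c("CPDA", "CPDB"),
                    replicates = 3L, noise_sd = 0.1, seed = 3,
                    effects = list(list(probes = probes[1:500],
                                        compound = "CPDA",
                                        dose_levels = "Middle",
                                        time_points = "4 day",
                                        log2fc = 2)))
  sim <- generate_dataset(cfg)
  tab <- build_group_matrix(sim$dataset,
                            make_groups(sim$dataset, compounds = "CPDA",
                                        dose_levels = "Middle",
                                        times = "4 day"))
  dev <- tab$values[probes[1:500], 1] - 2
  expect_equal(sd(dev), 0.1 * sqrt(2 / 3), tolerance = 0.15)
  expect_gte(mean(abs(dev) <= 0.2), 0.96)
  expect_lt(abs(mean(dev)), 0.02)
  # null probes stay near zero
  expect_lt(max(abs(tab$values[probes[501:600], 1])), 1)
})

test_that("generation is deterministic and seed-isolated", {
  sim1 <- generate_dataset(small_config(seed = 9))
  set.seed(999) # caller RNG state must not leak into the generator
  sim2 <- generate_dataset(small_config(seed = 9))
  expect_identical(sim1$dataset$intensities, sim2$dataset$intensities)
  expect_identical(sim1$truth$deg_sets, sim2$truth$deg_sets)
  sim3 <- generate_dataset(small_config(seed = 10))
  expect_false(identical(sim1$dataset$intensities,
                         sim3$dataset$intensities))
  # byte-identical files for identical seeds
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(sim1$dataset, d1); write_dataset(sim2$dataset, d2)
  for (f in c("metadata.tsv", "expression.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_dataset(small_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("default truth describes the planted design", {
  sim <- generate_dataset(sim_config(seed = 4))
  truth <- sim$truth
  expect_equal(truth$ranked_compound, "CPD01")
  expect_length(truth$consistent_down, 60L)
  expect_equal(sort(unique(truth$cluster_blocks$labels)), 1:3)
  # per-condition DEG sets: early block + down block at 4 day
  deg4 <- truth$deg_sets[["CPD01/Middle/4 day"]]
  expect_setequal(deg4, sprintf("P%05d", c(1:60, 121:180)))
  # heavier-tailed noise option runs
  simt <- generate_dataset(small_config(seed = 6, noise = "t"))
  expect_true(all(simt$dataset$intensities > 0))
})

test_that("collection generator plants the configured overlap", {
  universe <- sprintf("G%03d", 1:300)
  planted <- universe[1:50]
  gc <- generate_collection(universe, planted, n_categories = 10,
                            category_size = 30, overlap_rate = 1.0,
                            seed = 8)
  cat_members <- gc$collection$categories$planted$members
  expect_true(all(cat_members %in% planted))
  expect_equal(gc$truth$planted_category, "planted")
  expect_length(gc$collection$categories, 10L)
  # infeasible overlap errors
  expect_error(generate_collection(universe, universe[1:5],
                                   category_size = 30,
                                   overlap_rate = 1.0, seed = 8),
               "infeasible")
  # reproducible
  gc2 <- generate_collection(universe, planted, n_categories = 10,
                             category_size = 30, overlap_rate = 1.0,
                             seed = 8)
  expect_identical(gc$collection$categories, gc2$collection$categories)
})

test_that("filter/cluster/rank recover the planted truth end to end", {
  sim <- generate_dataset(sim_config(seed = 15))
  ds <- median_normalize(sim$dataset)
  groups <- make_groups(ds, compounds = "CPD01", dose_levels = "Middle")
  tab <- build_group_matrix(ds, groups)
  # per-time-point |log2FC| >= 1.5 extraction (OR over columns)
  masks <- lapply(colnames(tab$values), function(cl)
    apply_filter(tab$values[, cl], column_filter("lower_abs", 1.5)))
  got <- rownames(tab$values)[Reduce(`|`, masks)]
  truth_deg <- names(sim$truth$cluster_blocks$labels)
  expect_gte(mean(truth_deg %in% got), 0.95)             # sensitivity
  expect_lte(mean(!(got %in% truth_deg)), 0.05)          # FDR
  # consistent down-regulation recovers exactly the planted halved set
  con <- extract_consistent(tab, ratio = 0.5, direction = "down")
  expect_setequal(con$members, sim$truth$consistent_down)
})
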