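#' @name core-data
#' @title Expression dataset, sample groups, and fold-change conventions
#'
#' @description
#' The central container is a `tox_dataset`: a probes x samples matrix of
#' strictly positive normalized intensities joined to a per-sample metadata
#' table. Samples carry a compound, a dose level (Control/Low/Middle/High,
#' free-text levels allowed), an exposure time, organ, species, platform and
#' test type, plus a `control_group` key that ties every treated sample to
#' its matched vehicle-control samples (same compound vehicle, organ and
#' exposure time).
#'
#' Two display conventions matter throughout:
#' * fold changes are stored **prior to** the log2 transform: the fold of a
#'   treated sample is its intensity divided by the arithmetic mean of its
#'   matched control group's intensities, probe-wise;
#' * a group's displayed log2 value is `log2(mean(folds))` — the mean over
#'   the group's samples is taken first and the logarithm applied last, so
#'   combining doses/times/compounds into one group stays consistent. This
#'   is not the same as the mean of per-sample log2 folds.
NULL

# required metadata columns of the upload dialect
META_COLUMNS <- c("sample_id", "compound", "dose_level", "exposure_time",
                  "organ", "species", "platform", "test_type",
                  "control_group")

STANDARD_DOSE_LEVELS <- c("Control", "Low", "Middle", "High")

#' Construct an expression dataset
#'
#' @param intensities numeric matrix, probes x samples, strictly positive
#'   normalized intensities. Row names are probe IDs, column names sample
#'   IDs.
#' @param samples data.frame of sample metadata with columns
#'   `sample_id`, `compound`, `dose_level`, `exposure_time`, `organ`,
#'   `species`, `platform`, `test_type`, `control_group`. One row per
#'   column of `intensities`, matched by `sample_id`.
#' @return An object of class `tox_dataset` with elements `probes`,
#'   `samples` and `intensities` (columns ordered as in `samples`).
#' @export
#' @examples
#' m <- matrix(c(2, 4, 8, 5, 1, 3), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), compound = "cpdA",
#'                    dose_level = c("Control", "Middle"),
#'                    exposure_time = "4 day", organ = "liver",
#'                    species = "rat", platform = "Rat230_2",
#'                    test_type = "in_vivo", control_group = "g1")
#' ds <- tox_dataset(m, meta)
tox_dataset <- function(intensities, samples) {
  check_that(is.matrix(intensities) && is.numeric(intensities),
             "`intensities` must be a numeric matrix")
  check_that(is.data.frame(samples), "`samples` must be a data.frame")
  missing_cols <- setdiff(META_COLUMNS, names(samples))
  check_that(length(missing_cols) == 0L,
             "metadata is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  samples <- as.data.frame(lapply(samples[META_COLUMNS], as.character),
                           stringsAsFactors = FALSE)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  check_that(length(dup) == 0L, "duplicate sample ID(s): %s",
             paste(unique(dup), collapse = ", "))
  probes <- rownames(intensities)
  check_that(!is.null(probes) && !anyNA(probes),
             "`intensities` must have probe IDs as row names")
  dupp <- probes[duplicated(probes)]
  check_that(length(dupp) == 0L, "duplicate probe ID(s): %s",
             paste(unique(dupp), collapse = ", "))
  check_that(!is.null(colnames(intensities)),
             "`intensities` must have sample IDs as column names")
  only_meta <- setdiff(samples$sample_id, colnames(intensities))
  only_data <- setdiff(colnames(intensities), samples$sample_id)
  check_that(length(only_meta) == 0L && length(only_data) == 0L,
             "sample sets differ: %s%s",
             if (length(only_meta))
               paste0("only in metadata: ",
                      paste(only_meta, collapse = ", "), ". ") else "",
             if (length(only_data))
               paste0("only in data: ",
                      paste(only_data, collapse = ", ")) else "")
  intensities <- intensities[, samples$sample_id, drop = FALSE]
  bad <- which(!is.finite(intensities) | intensities <= 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-positive or non-finite intensity at probe '%s', sample '%s'%s",
      probes[bad[1L, 1L]], colnames(intensities)[bad[1L, 2L]],
      if (nrow(bad) > 1L)
        sprintf(" (and %d more)", nrow(bad) - 1L) else ""),
      call. = FALSE)
  }
  ds <- structure(list(probes = probes, samples = samples,
                       intensities = intensities),
                  class = "tox_dataset")
  validate_controls(ds)
  ds
}

# every control_group key must resolve to >=1 Control sample sharing
# compound, organ and exposure time with the treated samples that carry it
validate_controls <- function(ds) {
  s <- ds$samples
  is_ctrl <- s$dose_level == "Control"
  for (key in unique(s$control_group)) {
    members <- s[s$control_group == key, , drop = FALSE]
    ctl <- members[members$dose_level == "Control", , drop = FALSE]
    check_that(nrow(ctl) >= 1L,
               "control group '%s' has no Control-dose sample", key)
    check_that(length(unique(members$organ)) == 1L &&
               length(unique(members$exposure_time)) == 1L,
               paste0("control group '%s' mixes organs or exposure times; ",
                      "controls must be matched"), key)
  }
  invisible(ds)
}

#' @export
print.tox_dataset <- function(x, ...) {
  cat(sprintf("tox_dataset: %d probes x %d samples\n",
              length(x$probes), nrow(x$samples)))
  cat(sprintf("  compounds: %s\n",
              paste(unique(x$samples$compound), collapse = ", ")))
  cat(sprintf("  dose levels: %s; times: %s\n",
              paste(unique(x$samples$dose_level), collapse = "/"),
              paste(unique(x$samples$exposure_time), collapse = "/")))
  invisible(x)
}

#' Median-normalize every sample column
#'
#' Divides each sample column by its own median so that the per-column
#' median becomes 1 (for an even number of probes the median is the mean of
#' the two middle order statistics). This is the normalization applied to
#' "absolute value" intensities, and it is shared with the fold-change
#' route since a common scale factor cancels in treated/control ratios.
#'
#' @param dataset a [tox_dataset()].
#' @return A `tox_dataset` with normalized intensities.
#' @export
median_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "tox_dataset"))
  m <- dataset$intensities
  med <- apply(m, 2L, median)
  dataset$intensities <- sweep(m, 2L, med, "/")
  dataset
}

#' Fold change of one sample against its control group
#'
#' @param sample_values named numeric vector of intensities for one treated
#'   sample, indexed by probe.
#' @param control_values numeric matrix, probes x control samples, with
#'   row names matching `names(sample_values)`.
#' @return Numeric vector of folds (treated / mean(control)), probe-indexed.
#' @export
compute_fold <- function(sample_values, control_values) {
  check_that(is.matrix(control_values) && ncol(control_values) >= 1L,
             "control set must be a non-empty matrix")
  check_that(identical(names(sample_values), rownames(control_values)),
             "probe index mismatch between sample and controls")
  sample_values / rowMeans(control_values)
}

#' Group log2 value: mean of folds, then log2
#'
#' The group-level statistic is `log2(mean(folds))`: average the raw fold
#' values over all samples in the group first, apply the log transform
#' last. By Jensen's inequality this is always >= the mean of the
#' per-sample log2 folds, with equality only when all folds agree.
#'
#' @param fold_values numeric vector of positive fold values, one per
#'   sample in the group.
#' @return log2 of the arithmetic mean of `fold_values`.
#' @export
#' @examples
#' group_log2_value(c(1, 4)) # log2(2.5), not (0 + 2)/2
group_log2_value <- function(fold_values) {
  check_that(length(fold_values) >= 1L, "empty group: no fold values")
  check_that(all(is.finite(fold_values) & fold_values > 0),
             "fold values must be positive and finite")
  log2(mean(fold_values))
}

#' Define a sample group
#'
#' A named set of treated samples sharing user-chosen factor levels, with
#' its matched control samples.
#'
#' @param name group name (table column header).
#' @param sample_ids character vector of treated sample IDs (non-empty).
#' @param control_sample_ids character vector of control sample IDs,
#'   disjoint from `sample_ids`.
#' @param factors named list of factor -> level describing the group
#'   (e.g. `list(compound = "WY", dose_level = "Middle")`).
#' @return An object of class `tox_group`.
#' @export
sample_group <- function(name, sample_ids, control_sample_ids,
                         factors = list()) {
  check_that(is.character(name) && nzchar(name), "group name must be non-empty")
  sample_ids <- unique(as.character(sample_ids))
  control_sample_ids <- unique(as.character(control_sample_ids))
  check_that(length(sample_ids) >= 1L, "group '%s' has no samples", name)
  overlap <- intersect(sample_ids, control_sample_ids)
  check_that(length(overlap) == 0L,
             "group '%s': samples also listed as controls: %s", name,
             paste(overlap, collapse = ", "))
  structure(list(name = name, sample_ids = sample_ids,
                 control_sample_ids = control_sample_ids,
                 factors = factors),
            class = "tox_group")
}

#' Auto-define one group per compound x dose x time
#'
#' Builds a group for every non-control (compound, dose level, exposure
#' time) combination present in the dataset, attaching the matched
#' vehicle-control samples through the `control_group` key. Optional
#' arguments restrict the scope.
#'
#' @param dataset a [tox_dataset()].
#' @param compounds,dose_levels,times optional character vectors limiting
#'   the combinations considered.
#' @return List of [sample_group()] objects, named by group name
#'   (`"<compound>/<dose>/<time>"`), in compound, dose, time order.
#' @export
make_groups <- function(dataset, compounds = NULL, dose_levels = NULL,
                        times = NULL) {
  stopifnot(inherits(dataset, "tox_dataset"))
  s <- dataset$samples
  s <- s[s$dose_level != "Control", , drop = FALSE]
  if (!is.null(compounds)) s <- s[s$compound %in% compounds, , drop = FALSE]
  if (!is.null(dose_levels)) s <- s[s$dose_level %in% dose_levels, , drop = FALSE]
  if (!is.null(times)) s <- s[s$exposure_time %in% times, , drop = FALSE]
  check_that(nrow(s) > 0L, "no treated samples in the requested scope")
  key <- paste(s$compound, s$dose_level, s$exposure_time, sep = "/")
  all_meta <- dataset$samples
  groups <- lapply(unique(key), function(k) {
    rows <- s[key == k, , drop = FALSE]
    ctl_keys <- unique(rows$control_group)
    ctl <- all_meta$sample_id[all_meta$control_group %in% ctl_keys &
                              all_meta$dose_level == "Control"]
    sample_group(k, rows$sample_id, ctl,
                 factors = list(compound = rows$compound[1L],
                                dose_level = rows$dose_level[1L],
                                exposure_time = rows$exposure_time[1L]))
  })
  names(groups) <- unique(key)
  groups
}

# folds for an explicit set of treated samples against their control groups
fold_for_samples <- function(dataset, sample_ids, control_ids) {
  m <- dataset$intensities
  ctrl_mean <- rowMeans(m[, control_ids, drop = FALSE])
  m[, sample_ids, drop = FALSE] / ctrl_mean
}

#' Per-sample fold matrix for a set of groups
#'
#' Computes, for every treated sample of every group, the probe-wise ratio
#' of its intensity to the arithmetic mean of the group's matched control
#' samples. These are the "stored prior to log2" fold values; the
#' individual-sample export writes exactly this matrix.
#'
#' @param dataset a [tox_dataset()].
#' @param groups list of [sample_group()] objects.
#' @return An object of class `tox_fold_matrix`: list with `probes`,
#'   `samples` and a positive `folds` matrix (probes x treated samples).
#' @export
build_fold_matrix <- function(dataset, groups) {
  stopifnot(inherits(dataset, "tox_dataset"))
  groups <- as_group_list(groups)
  check_group_samples(dataset, groups)
  cols <- lapply(groups, function(g)
    fold_for_samples(dataset, g$sample_ids, g$control_sample_ids))
  folds <- do.call(cbind, cols)
  # a sample may appear in several groups; keep its first occurrence
  folds <- folds[, !duplicated(colnames(folds)), drop = FALSE]
  structure(list(probes = dataset$probes, samples = colnames(folds),
                 folds = folds),
            class = "tox_fold_matrix")
}

as_group_list <- function(groups) {
  if (inherits(groups, "tox_group")) groups <- list(groups)
  check_that(is.list(groups) && length(groups) > 0L &&
             all(vapply(groups, inherits, logical(1L), "tox_group")),
             "`groups` must be a non-empty list of tox_group objects")
  if (is.null(names(groups)))
    names(groups) <- vapply(groups, `[[`, character(1L), "name")
  groups
}

check_group_samples <- function(dataset, groups) {
  known <- dataset$samples$sample_id
  offenders <- unlist(lapply(groups, function(g)
    setdiff(c(g$sample_ids, g$control_sample_ids), known)))
  check_that(length(offenders) == 0L,
             "unknown sample ID(s) in group definitions: %s",
             paste(unique(offenders), collapse = ", "))
  invisible(TRUE)
}

#' Build the group table (probes x groups)
#'
#' The main data table: one column per sample group, one row per probe.
#' In `"log2_fold"` mode each cell is the group log2 value — the mean of
#' the per-sample folds against the group's matched controls, log2 applied
#' last (see [group_log2_value()]). In `"absolute"` mode each cell is the
#' plain mean of the group's (median-normalized) intensities.
#'
#' @param dataset a [tox_dataset()].
#' @param groups list of [sample_group()] objects.
#' @param mode `"log2_fold"` (default) or `"absolute"`.
#' @return An object of class `tox_group_table`: list with `values`
#'   (probes x groups matrix), `folds` (mean-fold matrix, log2_fold mode
#'   only), `n_samples` (per group), `mode` and `groups`.
#' @export
build_group_matrix <- function(dataset, groups,
                               mode = c("log2_fold", "absolute")) {
  stopifnot(inherits(dataset, "tox_dataset"))
  mode <- match.arg(mode)
  groups <- as_group_list(groups)
  check_group_samples(dataset, groups)
  n_samples <- vapply(groups, function(g) length(g$sample_ids), integer(1L))
  if (mode == "log2_fold") {
    folds <- vapply(groups, function(g) {
      f <- fold_for_samples(dataset, g$sample_ids, g$control_sample_ids)
      rowMeans(f)
    }, numeric(length(dataset$probes)))
    folds <- matrix(folds, nrow = length(dataset$probes),
                    dimnames = list(dataset$probes, names(groups)))
    values <- log2(folds)
  } else {
    folds <- NULL
    values <- vapply(groups, function(g)
      rowMeans(dataset$intensities[, g$sample_ids, drop = FALSE]),
      numeric(length(dataset$probes)))
    values <- matrix(values, nrow = length(dataset$probes),
                     dimnames = list(dataset$probes, names(groups)))
  }
  structure(list(values = values, folds = folds, n_samples = n_samples,
                 mode = mode, groups = groups),
            class = "tox_group_table")
}

#' @export
print.tox_group_table <- function(x, ...) {
  cat(sprintf("tox_group_table (%s): %d probes x %d groups\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}
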