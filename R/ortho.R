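#' @name ortho
#' @title Orthologous display mode: cross-species row aggregation
#'
#' @description
#' When sample groups span more than one platform (hence species), probes
#' cannot be compared row by row. An ortholog map - precomputed elsewhere,
#' e.g. from protein sequence similarity - assigns probes of several
#' platforms to ortholog sets. Each set becomes a single table row whose
#' cell for a group is the *median* of the per-probe group averages of the
#' set's members on that group's platform ("a median of averages"; the
#' group average itself is the normal-mode cell value).
NULL

#' Construct an ortholog map
#'
#' @param sets data.frame with columns `set_id`, `platform`, `probe_id`.
#' @param provenance free-text note on how the orthology was derived.
#' @return An object of class `tox_ortho_map`.
#' @export
ortholog_map <- function(sets, provenance = "") {
  check_that(is.data.frame(sets) &&
             all(c("set_id", "platform", "probe_id") %in% names(sets)),
             "`sets` needs columns set_id, platform, probe_id")
  sets <- as.data.frame(lapply(sets[c("set_id", "platform", "probe_id")],
                               as.character), stringsAsFactors = FALSE)
  key <- paste(sets$platform, sets$probe_id)
  dup <- sets$probe_id[duplicated(key) |
                       duplicated(key, fromLast = TRUE)]
  multi <- tapply(sets$set_id, key, function(s) length(unique(s)))
  check_that(all(multi == 1L),
             "probe(s) assigned to more than one ortholog set: %s",
             paste(unique(dup), collapse = ", "))
  sets <- sets[!duplicated(key), , drop = FALSE]
  structure(list(sets = sets, provenance = provenance),
            class = "tox_ortho_map")
}

#' Aggregate one ortholog set cell
#'
#' The cell for (ortholog set, group) is the median of the per-probe group
#' averages of the contributing probes (even counts: mean of the two
#' middle values). No contributing probe means a missing cell (`NA`,
#' never 0).
#'
#' @param group_values numeric vector of per-probe group averages for the
#'   set's probes on the group's platform.
#' @return The median, or `NA` when no value contributes.
#' @export
#' @examples
#' aggregate_ortholog_row(c(1, 2, 9)) # 2, the median, not the mean 4
aggregate_ortholog_row <- function(group_values) {
  group_values <- group_values[!is.na(group_values)]
  if (length(group_values) == 0L) return(NA_real_)
  median(group_values)
}

#' Build the ortholog-set x group table
#'
#' Columns are the union of the group names across the platform tables,
#' in first-appearance order. The cell for (set, group) pools the
#' per-probe group averages of the set's members from **every** platform
#' table carrying that group column and takes their median - so a group
#' present on a single platform aggregates that platform's probes, while
#' a group name shared across platforms is compared on a common
#' cross-species row.
#'
#' @param tables named list platform -> [build_group_matrix()] result (or
#'   plain probes x groups matrix) for the groups of that platform. At
#'   least two platforms are required - with a single platform the
#'   orthologous mode is not applicable and normal mode should be used.
#' @param map an [ortholog_map()].
#' @return Matrix ortholog sets x groups; rows are ortholog sets with at
#'   least one member value, cells without a contributing probe are `NA`.
#' @export
build_ortho_table <- function(tables, map) {
  stopifnot(inherits(map, "tox_ortho_map"))
  check_that(is.list(tables) && !is.null(names(tables)),
             "`tables` must be a named list keyed by platform")
  check_that(length(tables) >= 2L,
             paste0("orthologous mode needs groups from >= 2 platforms; ",
                    "use the normal per-probe table for a single platform"))
  mats <- lapply(tables, function(t)
    if (inherits(t, "tox_group_table")) t$values else t)
  set_ids <- unique(map$sets$set_id)
  cols <- unique(unlist(lapply(mats, colnames)))
  out <- matrix(NA_real_, nrow = length(set_ids), ncol = length(cols),
                dimnames = list(set_ids, cols))
  for (s in set_ids) {
    members <- map$sets[map$sets$set_id == s, , drop = FALSE]
    for (g in cols) {
      vals <- unlist(lapply(names(mats), function(p) {
        m <- mats[[p]]
        probes <- intersect(members$probe_id[members$platform == p],
                            rownames(m))
        if (length(probes) == 0L || !(g %in% colnames(m)))
          return(numeric())
        m[probes, g]
      }))
      out[s, g] <- aggregate_ortholog_row(vals)
    }
  }
  keep <- rowSums(!is.na(out)) > 0L
  out[keep, , drop = FALSE]
}
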