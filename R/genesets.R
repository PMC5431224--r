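#' @name genesets
#' @title Gene sets, column filters, and set algebra
#'
#' @description
#' A gene set is a named, ordered list of unique probe/gene IDs together
#' with a provenance log describing the filters, tests or clusters that
#' produced it. Gene sets are the currency passed between the stages of an
#' analysis: filtering a table yields one, clustering yields one per
#' cluster, enrichment and ranking consume them.
NULL

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param members character vector of probe/gene IDs; duplicates are
#'   removed keeping first occurrence (order is meaningful).
#' @param provenance character vector of free-text provenance lines.
#' @return An object of class `tox_geneset`.
#' @export
gene_set <- function(name, members, provenance = character()) {
  check_that(is.character(name) && length(name) == 1L && nzchar(name),
             "gene set name must be a non-empty string")
  members <- as.character(members)
  members <- members[!duplicated(members)]
  structure(list(name = name, members = members,
                 provenance = as.character(provenance)),
            class = "tox_geneset")
}

#' @export
print.tox_geneset <- function(x, ...) {
  cat(sprintf("tox_geneset '%s': %d members\n", x$name, length(x$members)))
  for (p in x$provenance) cat("  # ", p, "\n", sep = "")
  invisible(x)
}

#' @export
length.tox_geneset <- function(x) length(x$members)

#' Column filter specification
#'
#' Four filter kinds are available for every table column: an upper bound
#' (`v <= t`), an upper bound on absolute value (`|v| <= t`), a lower bound
#' (`v >= t`), and a lower bound on absolute value (`|v| >= t`). All bounds
#' are inclusive. An inactive filter passes everything.
#'
#' @param kind one of `"upper"`, `"upper_abs"`, `"lower"`, `"lower_abs"`.
#' @param threshold finite numeric threshold.
#' @param active logical; inactive filters are identity.
#' @return An object of class `tox_filter`.
#' @export
column_filter <- function(kind = c("upper", "upper_abs", "lower", "lower_abs"),
                          threshold, active = TRUE) {
  kind <- match.arg(kind)
  check_that(is.numeric(threshold) && length(threshold) == 1L &&
             is.finite(threshold), "filter threshold must be finite")
  structure(list(kind = kind, threshold = threshold,
                 active = isTRUE(active)),
            class = "tox_filter")
}

#' Apply a column filter to a vector of values
#'
#' Missing (`NA`) values fail any active filter; an inactive filter passes
#' every row including missing ones.
#'
#' @param values numeric vector (probe-indexed).
#' @param filter a [column_filter()].
#' @return Logical mask, same length as `values`.
#' @export
apply_filter <- function(values, filter) {
  stopifnot(inherits(filter, "tox_filter"))
  if (!filter$active) return(rep(TRUE, length(values)))
  t <- filter$threshold
  mask <- switch(filter$kind,
    upper     = values <= t,
    upper_abs = abs(values) <= t,
    lower     = values >= t,
    lower_abs = abs(values) >= t)
  mask[is.na(mask)] <- FALSE
  mask
}

#' Filter a group table into a gene set
#'
#' Applies every active filter to its column and keeps the rows passing
#' **all** of them (conjunction). Row order of the table is preserved.
#' Extra numeric columns (e.g. p-value columns from [stat_column()]) can be
#' supplied through `extra`.
#'
#' @param table a [build_group_matrix()] result, or a plain numeric matrix
#'   with probe row names.
#' @param filters named list of [column_filter()]s; names are column names
#'   of the table (or of `extra`).
#' @param extra optional named list of additional probe-indexed numeric
#'   vectors usable as filter columns.
#' @param name name for the resulting gene set.
#' @return A [gene_set()] whose provenance records each applied filter. An
#'   empty result is allowed and signalled with a warning.
#' @export
filter_table <- function(table, filters, extra = list(),
                         name = "filtered") {
  values <- if (inherits(table, "tox_group_table")) table$values else table
  check_that(is.matrix(values), "`table` must be a group table or matrix")
  check_that(length(filters) > 0L && !is.null(names(filters)),
             "`filters` must be a named list")
  probes <- rownames(values)
  mask <- rep(TRUE, nrow(values))
  prov <- character()
  for (col in names(filters)) {
    f <- filters[[col]]
    stopifnot(inherits(f, "tox_filter"))
    v <- if (col %in% colnames(values)) {
      values[, col]
    } else if (col %in% names(extra)) {
      x <- extra[[col]]
      if (!is.null(names(x))) x[probes] else x
    } else {
      stop(sprintf("unknown filter column '%s'", col), call. = FALSE)
    }
    mask <- mask & apply_filter(v, f)
    if (f$active)
      prov <- c(prov, sprintf("filter %s: %s %s", col, f$kind,
                              format(f$threshold)))
  }
  if (!any(mask)) warning("filter result is empty", call. = FALSE)
  gene_set(name, probes[mask], provenance = prov)
}

#' Probes consistently regulated across all time points
#'
#' Implements the "half of or less than control at all time points"
#' extraction rule. In `"down"` mode a probe is kept iff its group-level
#' fold is `<= ratio` at **every** time point (boundary inclusive: a fold
#' of exactly 0.5 passes at ratio 0.5); in `"up"` mode iff the fold is
#' `>= 1/ratio` everywhere.
#'
#' @param folds numeric matrix of group mean folds (pre-log), probes x time
#'   points, restricted to one compound/dose. A `tox_group_table` in
#'   log2_fold mode is also accepted (its `folds` element is used).
#' @param ratio positive fold threshold, default 0.5.
#' @param direction `"down"` or `"up"`.
#' @param name gene-set name.
#' @return A [gene_set()] of the consistently regulated probes. Probes with
#'   a missing value at any time point are excluded and reported in the
#'   provenance.
#' @export
extract_consistent <- function(folds, ratio = 0.5,
                               direction = c("down", "up"),
                               name = NULL) {
  direction <- match.arg(direction)
  if (inherits(folds, "tox_group_table")) {
    check_that(identical(folds$mode, "log2_fold"),
               "consistent-regulation extraction needs a fold-mode table")
    folds <- folds$folds
  }
  check_that(is.matrix(folds) && ncol(folds) >= 1L,
             "`folds` must have at least one time point column")
  check_that(is.numeric(ratio) && ratio > 0, "`ratio` must be positive")
  complete <- rowSums(is.na(folds)) == 0L
  keep <- if (direction == "down") {
    complete & rowSums(folds > ratio, na.rm = TRUE) == 0L
  } else {
    complete & rowSums(folds < 1 / ratio, na.rm = TRUE) == 0L
  }
  prov <- sprintf("consistent %s-regulation: fold %s %s at all %d time points",
                  direction, if (direction == "down") "<=" else ">=",
                  format(if (direction == "down") ratio else 1 / ratio),
                  ncol(folds))
  n_missing <- sum(!complete)
  if (n_missing > 0L)
    prov <- c(prov, sprintf("%d probe(s) excluded for missing time points",
                            n_missing))
  gene_set(name %||% sprintf("consistent_%s", direction),
           rownames(folds)[keep], provenance = prov)
}

#' Set algebra on gene sets
#'
#' Union, intersection and difference with deterministic ordering: members
#' of `a` first (in `a`'s order), then members contributed by `b` in `b`'s
#' order.
#'
#' @param a,b [gene_set()] objects.
#' @param op `"union"`, `"intersect"` or `"difference"`.
#' @param name optional name for the result.
#' @return A [gene_set()].
#' @export
geneset_algebra <- function(a, b, op = c("union", "intersect", "difference"),
                            name = NULL) {
  stopifnot(inherits(a, "tox_geneset"), inherits(b, "tox_geneset"))
  op <- match.arg(op)
  members <- switch(op,
    union      = c(a$members, setdiff(b$members, a$members)),
    intersect  = a$members[a$members %in% b$members],
    difference = setdiff(a$members, b$members))
  gene_set(name %||% sprintf("%s_%s_%s", a$name, op, b$name), members,
           provenance = sprintf("%s(%s [%d], %s [%d])", op,
                                a$name, length(a$members),
                                b$name, length(b$members)))
}
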