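#' @name ranking
#' @title Compound ranking by consistent regulation of a query gene set
#'
#' @description
#' Orders compounds by how consistently they up- or down-regulate a query
#' gene set across the scoped experimental conditions. The score is the
#' mean signed log2 fold over the query genes and conditions:
#' `mean(-log2 fold)` in total-downregulation mode, `mean(+log2 fold)` in
#' total-upregulation mode, so higher is always a stronger match. The
#' scorer is pluggable (`scorer` argument) since other aggregations
#' (min/max over time points, correlation to a reference curve) are
#' reasonable alternatives.
NULL

#' Compound ranking query
#'
#' @param gene_set non-empty [gene_set()] of query probes/genes.
#' @param mode `"total_downregulation"` or `"total_upregulation"`.
#' @param dose_level dose level to score on (default `"Middle"`).
#' @return An object of class `tox_rank_query`.
#' @export
ranking_query <- function(gene_set,
                          mode = c("total_downregulation",
                                   "total_upregulation"),
                          dose_level = "Middle") {
  stopifnot(inherits(gene_set, "tox_geneset"))
  mode <- match.arg(mode)
  check_that(length(gene_set$members) > 0L, "query gene set is empty")
  structure(list(gene_set = gene_set, mode = mode,
                 dose_level = dose_level),
            class = "tox_rank_query")
}

# default scorer: mean signed log2 fold over genes x conditions
mean_log2_scorer <- function(log2_values, mode) {
  sign <- if (mode == "total_downregulation") -1 else 1
  mean(sign * log2_values)
}

#' Score one compound against a ranking query
#'
#' @param log2_values numeric matrix of group log2 fold values restricted
#'   to one compound: probes x scoped conditions (e.g. time points).
#' @param query a [ranking_query()].
#' @param scorer function `(log2_values, mode) -> score`; the default is
#'   the mean signed log2 fold.
#' @return List with `score`, `genes_used`, `conditions_used`. Query genes
#'   missing from the matrix are dropped with a warning; no overlap at all
#'   is an error (the caller excludes such compounds from the ranking).
#' @export
compound_score <- function(log2_values, query,
                           scorer = mean_log2_scorer) {
  stopifnot(inherits(query, "tox_rank_query"))
  check_that(is.matrix(log2_values), "`log2_values` must be a matrix")
  genes <- unique(query$gene_set$members)
  present <- intersect(genes, rownames(log2_values))
  if (length(present) == 0L) {
    stop("no overlap between query genes and compound data", call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning(sprintf("%d query gene(s) missing for this compound dropped",
                    length(genes) - length(present)), call. = FALSE)
  }
  m <- log2_values[present, , drop = FALSE]
  list(score = scorer(m, query$mode),
       genes_used = length(present), conditions_used = ncol(m))
}

#' Rank compounds by a query gene set
#'
#' Builds, for every compound in scope, the matrix of group log2 values of
#' the query genes over the compound's conditions, scores it, and returns
#' the compounds in descending score order with a deterministic
#' alphabetical tie-break.
#'
#' @param table a [build_group_matrix()] result in log2_fold mode whose
#'   groups carry a `compound` factor (as produced by [make_groups()]).
#' @param query a [ranking_query()]; its `dose_level` restricts the scoped
#'   groups when the groups carry a `dose_level` factor.
#' @param scorer see [compound_score()].
#' @return data.frame of class `tox_ranking`: `rank`, `compound`, `score`,
#'   `genes_used`, `conditions_used`. Compounds with no query-gene overlap
#'   are excluded and listed in the `"excluded"` attribute.
#' @export
rank_compounds <- function(table, query, scorer = mean_log2_scorer) {
  stopifnot(inherits(table, "tox_group_table"),
            inherits(query, "tox_rank_query"))
  check_that(identical(table$mode, "log2_fold"),
             "ranking needs a log2_fold group table")
  fac <- lapply(table$groups, `[[`, "factors")
  compound <- vapply(fac, function(f)
    as.character(f$compound %||% NA_character_), character(1L))
  check_that(!anyNA(compound),
             "every group must carry a `compound` factor")
  dose <- vapply(fac, function(f)
    as.character(f$dose_level %||% query$dose_level), character(1L))
  in_scope <- dose == query$dose_level
  check_that(any(in_scope), "no groups at dose level '%s'", query$dose_level)
  compounds <- sort(unique(compound[in_scope]))
  check_that(length(compounds) >= 2L,
             "ranking needs >= 2 compounds in scope")
  excluded <- character()
  rows <- lapply(compounds, function(cp) {
    cols <- which(in_scope & compound == cp)
    m <- table$values[, cols, drop = FALSE]
    s <- tryCatch(suppressWarnings(compound_score(m, query, scorer)),
                  error = function(e) NULL)
    if (is.null(s)) { excluded <<- c(excluded, cp); return(NULL) }
    data.frame(compound = cp, score = s$score, genes_used = s$genes_used,
               conditions_used = s$conditions_used,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  check_that(length(rows) > 0L, "no compound overlaps the query gene set")
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$compound), , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  class(res) <- c("tox_ranking", "data.frame")
  attr(res, "excluded") <- excluded
  attr(res, "mode") <- query$mode
  res
}
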