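#' @name enrichment
#' @title Hypergeometric gene-set enrichment against GMT collections
#'
#' @description
#' Over-representation analysis of a query gene set against an annotation
#' collection (pathways, GO terms, GOSlim, integrated pathway clusters)
#' loaded from GMT. For a universe of `N` genes of which `K` belong to a
#' category, and a query of `n` genes with `k` in the category, the raw
#' p-value is the one-sided hypergeometric upper tail `P(X >= k)`.
#' p-values are Benjamini-Hochberg adjusted across tested categories by
#' default. The per-cluster quick summary ([top_feature_per_cluster()])
#' reports the single most enriched category per cluster with its *raw*
#' p-value, mirroring the popup shown while tuning a dendrogram cutoff.
NULL

#' Construct an annotation collection
#'
#' @param name collection name.
#' @param categories named list: category ID -> list(description, members)
#'   or -> character vector of member IDs.
#' @param feature_type one of `"pathway"`, `"go_term"`, `"goslim"`,
#'   `"ipc"`, `"other"`.
#' @return An object of class `tox_collection`.
#' @export
annotation_collection <- function(name, categories,
                                  feature_type = c("pathway", "go_term",
                                                   "goslim", "ipc",
                                                   "other")) {
  feature_type <- match.arg(feature_type)
  check_that(length(categories) > 0L && !is.null(names(categories)),
             "`categories` must be a non-empty named list")
  categories <- lapply(categories, function(cat) {
    if (is.character(cat)) cat <- list(description = "", members = cat)
    cat$members <- unique(as.character(cat$members))
    cat$description <- as.character(cat$description %||% "")
    cat
  })
  structure(list(name = name, feature_type = feature_type,
                 categories = categories),
            class = "tox_collection")
}

#' @export
print.tox_collection <- function(x, ...) {
  cat(sprintf("tox_collection '%s' (%s): %d categories\n",
              x$name, x$feature_type, length(x$categories)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` is the overlap between a random `n`-subset of a
#' universe of size `N` and a fixed category of size `K`. Computed by
#' summing the probability mass on the log scale, which is stable for
#' universes up to at least 1e5.
#'
#' @param N universe size.
#' @param K category size (`K <= N`).
#' @param n query size (`n <= N`).
#' @param k observed overlap (`k <= min(K, n)`).
#' @return The exact upper-tail probability.
#' @export
#' @examples
#' hypergeom_tail(10, 4, 5, 4) # 6/252
hypergeom_tail <- function(N, K, n, k) {
  check_that(all(c(N, K, n, k) >= 0) && k <= n && n <= N && K <= N &&
             k <= K && N - K >= n - k,
             "inconsistent counts: need 0 <= k <= min(K, n), n <= N, K <= N")
  if (k <= 0) return(1)
  x <- k:min(K, n)
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, sum(exp(lp)))
}

# p-value adjustment kept explicit so the choices are visible
adjust_p <- function(p, method = c("bh", "holm", "none")) {
  method <- match.arg(method)
  switch(method,
         none = p,
         bh = stats::p.adjust(p, method = "BH"),
         holm = stats::p.adjust(p, method = "holm"))
}

#' Enrichment of a query gene set against a collection
#'
#' Query genes absent from the universe are dropped with a warning. One
#' row is produced per category with at least one universe member; rows
#' are sorted by raw p ascending (ties by category ID). When a
#' probe-to-gene map is supplied, probes are collapsed so that a gene
#' counts once regardless of probe multiplicity.
#'
#' @param query a [gene_set()] (or character vector of IDs).
#' @param universe a [gene_set()] or character vector: all IDs that could
#'   have been selected (typically every probe/gene on the platform).
#' @param collection an [annotation_collection()].
#' @param adjust `"bh"` (default), `"holm"` or `"none"`.
#' @param probe_gene optional named character vector probe -> gene applied
#'   to query, universe and category members before testing.
#' @return A data.frame of class `tox_enrichment` with columns
#'   `category`, `description`, `N`, `K`, `n`, `k`, `p`, `p_adjusted`.
#' @export
enrich <- function(query, universe, collection,
                   adjust = c("bh", "holm", "none"), probe_gene = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "tox_collection"))
  qids <- if (inherits(query, "tox_geneset")) query$members else
    as.character(query)
  uids <- if (inherits(universe, "tox_geneset")) universe$members else
    as.character(universe)
  map_ids <- function(ids) {
    if (is.null(probe_gene)) return(unique(ids))
    mapped <- probe_gene[ids]
    unique(mapped[!is.na(mapped)])
  }
  qids <- map_ids(qids); uids <- map_ids(uids)
  dropped <- setdiff(qids, uids)
  if (length(dropped) > 0L) {
    warning(sprintf("%d query gene(s) absent from the universe dropped",
                    length(dropped)), call. = FALSE)
    qids <- intersect(qids, uids)
  }
  check_that(length(qids) > 0L, "effective query is empty")
  N <- length(uids); n <- length(qids)
  rows <- lapply(names(collection$categories), function(id) {
    cat <- collection$categories[[id]]
    members <- map_ids(cat$members)
    members <- intersect(members, uids)
    if (length(members) == 0L) return(NULL)
    K <- length(members)
    k <- length(intersect(qids, members))
    data.frame(category = id, description = cat$description,
               N = N, K = K, n = n, k = k,
               p = hypergeom_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  check_that(length(rows) > 0L,
             "no collection category overlaps the universe")
  res <- do.call(rbind, rows)
  res$p_adjusted <- adjust_p(res$p, adjust)
  res <- res[order(res$p, res$category), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tox_enrichment", "data.frame")
  attr(res, "adjust") <- adjust
  res
}

#' Most enriched feature per cluster
#'
#' For every cluster of a partition, reports the single category with the
#' smallest raw p-value (ties broken by larger overlap `k`, then by
#' lexicographic category ID). Clusters overlapping no tested category
#' report `"none"` with p = NA.
#'
#' @param partition a [cut_dendrogram()] result (or a named list of
#'   member-ID vectors).
#' @param universe a [gene_set()] or character vector (see [enrich()]).
#' @param collection an [annotation_collection()].
#' @param probe_gene optional probe -> gene map (see [enrich()]).
#' @return data.frame with columns `cluster`, `category`, `description`,
#'   `k`, `p`.
#' @export
top_feature_per_cluster <- function(partition, universe, collection,
                                    probe_gene = NULL) {
  clusters <- if (inherits(partition, "tox_partition"))
    partition$clusters else partition
  check_that(length(clusters) > 0L, "empty partition")
  rows <- lapply(names(clusters), function(nm) {
    res <- tryCatch(
      suppressWarnings(enrich(clusters[[nm]], universe, collection,
                              adjust = "none", probe_gene = probe_gene)),
      error = function(e) NULL)
    if (!is.null(res)) res <- res[res$k >= 1L, , drop = FALSE]
    if (is.null(res) || nrow(res) == 0L) {
      return(data.frame(cluster = nm, category = "none", description = "",
                        k = NA_integer_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    res <- res[order(res$p, -res$k, res$category), , drop = FALSE]
    data.frame(cluster = nm, category = res$category[1L],
               description = res$description[1L], k = res$k[1L],
               p = res$p[1L], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
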