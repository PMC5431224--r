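#' @name clustering
#' @title Hierarchical clustering with dendrogram-cutoff partitioning
#'
#' @description
#' Genes (table rows) and sample groups (table columns) are clustered
#' agglomeratively; a height cutoff on the gene dendrogram then partitions
#' the clustered genes into disjoint clusters, each emitted as a gene set
#' named `cluster1..K` in dendrogram (leaf) order. The default
#' configuration is Ward's method on squared dissimilarities (`ward_d2`)
#' with Pearson correlation distance, the usual choice for clustering
#' fold-change profiles where the *shape* of the dose/time response
#' matters more than its magnitude. For performance, clustering is limited
#' to 1000 gene rows or fewer.
NULL

MAX_CLUSTER_GENES <- 1000L

linkage_codes <- c(single = 0L, complete = 1L, average = 2L, ward_d2 = 3L)

#' Pearson correlation distance between table rows
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of rows
#' `i` and `j`; the range is `[0, 2]` with 0 for perfectly correlated and
#' 2 for perfectly anti-correlated profiles.
#'
#' @param table numeric matrix (probes x groups) with >= 2 columns.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(table) {
  check_that(is.matrix(table) && ncol(table) >= 2L,
             "Pearson distance needs a matrix with >= 2 columns")
  v <- row_vars(table)
  const <- which(v == 0 | !is.finite(v))
  if (length(const) > 0L) {
    ids <- rownames(table)[const] %||% as.character(const)
    stop(sprintf(
      "correlation undefined for constant row(s): %s",
      paste(utils::head(ids, 5L), collapse = ", ")), call. = FALSE)
  }
  d <- 1 - cor(t(table))
  d[d < 0] <- 0; d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Clustering configuration
#'
#' @param method linkage: `"ward_d2"` (default), `"average"`,
#'   `"complete"` or `"single"`.
#' @param distance `"pearson"` (correlation distance, default) or
#'   `"euclidean"`.
#' @param axis which axes to cluster: `"rows"`, `"columns"` or `"both"`.
#' @param max_genes row-count limit (default 1000).
#' @return An object of class `tox_clust_config`.
#' @export
clustering_config <- function(method = c("ward_d2", "average", "complete",
                                         "single"),
                              distance = c("pearson", "euclidean"),
                              axis = c("both", "rows", "columns"),
                              max_genes = MAX_CLUSTER_GENES) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  axis <- match.arg(axis)
  check_that(is.numeric(max_genes) && max_genes > 0,
             "`max_genes` must be positive")
  structure(list(method = method, distance = distance, axis = axis,
                 max_genes = as.integer(max_genes)),
            class = "tox_clust_config")
}

#' Agglomerative clustering of a distance matrix
#'
#' Runs the Lance-Williams recurrence for the chosen linkage. `ward_d2`
#' follows the Murtagh-Legendre definition: the update operates on squared
#' dissimilarities and merge heights are reported on the original distance
#' scale. Ties on the minimal distance are broken deterministically
#' (lexicographically smallest position pair), so runs are reproducible.
#'
#' @param dist_matrix symmetric numeric matrix with zero diagonal; row
#'   names are used as leaf labels.
#' @param method linkage method (see [clustering_config()]).
#' @param max_genes leaf-count limit; more leaves raise a size-limit error.
#' @return An object of class `tox_dendrogram`: list with `merge`
#'   (hclust-convention merge matrix), `height` (non-decreasing for these
#'   monotone linkages), `order` (leaf order for display), `labels`,
#'   `method`.
#' @export
hierarchical_cluster <- function(dist_matrix,
                                 method = c("ward_d2", "average",
                                            "complete", "single"),
                                 max_genes = MAX_CLUSTER_GENES) {
  method <- match.arg(method)
  check_that(is.matrix(dist_matrix) && nrow(dist_matrix) == ncol(dist_matrix),
             "`dist_matrix` must be a square matrix")
  n <- nrow(dist_matrix)
  check_that(n >= 2L, "need at least two leaves to cluster")
  if (n > max_genes) {
    stop(sprintf(
      "size limit: clustering is limited to sets of %d genes or less (got %d)",
      as.integer(max_genes), n), call. = FALSE)
  }
  check_that(max(abs(dist_matrix - t(dist_matrix))) < 1e-8 &&
             all(abs(diag(dist_matrix)) < 1e-12),
             "`dist_matrix` must be symmetric with a zero diagonal")
  res <- cpp_linkage(dist_matrix, linkage_codes[[method]])
  labels <- rownames(dist_matrix) %||% as.character(seq_len(n))
  structure(list(merge = res$merge, height = as.numeric(res$height),
                 order = merge_order(res$merge), labels = labels,
                 n_leaves = n, method = method),
            class = "tox_dendrogram")
}

# leaf display order by iterative left-to-right traversal of the merges
merge_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- nrow(merge)           # start at the root merge
  ord <- integer(0)
  while (length(stack) > 0L) {
    node <- stack[[1L]]; stack <- stack[-1L]
    if (node < 0L) {
      ord <- c(ord, -node)
    } else {
      stack <- c(merge[node, 1L], merge[node, 2L], stack)
    }
  }
  ord
}

#' @export
print.tox_dendrogram <- function(x, ...) {
  cat(sprintf("tox_dendrogram: %d leaves, %s linkage, root height %.4g\n",
              x$n_leaves, x$method, max(x$height)))
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x a `tox_dendrogram`.
#' @param ... unused.
#' @return A `stats::hclust` object (for plotting, `cophenetic()`, etc.).
#' @export
as.hclust.tox_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Cut a dendrogram at a height cutoff
#'
#' Two leaves share a cluster iff their lowest common merge has height
#' `<= cutoff` (boundary merges are joined). Clusters are numbered
#' `cluster1..K` in dendrogram leaf order, so the partition reads off the
#' heatmap top to bottom. Cluster count is non-increasing in the cutoff.
#'
#' @param dend a [hierarchical_cluster()] result.
#' @param cutoff finite height threshold.
#' @return An object of class `tox_partition`: list with `cutoff`,
#'   `assignment` (named integer vector leaf -> cluster index) and
#'   `clusters` (named list of leaf-label vectors).
#' @export
cut_dendrogram <- function(dend, cutoff) {
  stopifnot(inherits(dend, "tox_dendrogram"))
  check_that(is.numeric(cutoff) && length(cutoff) == 1L && is.finite(cutoff),
             "`cutoff` must be a finite number")
  n <- dend$n_leaves
  # union-find over merges at height <= cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_node <- integer(n - 1L)  # representative leaf per merge node
  for (m in seq_len(n - 1L)) {
    l <- dend$merge[m, 1L]; r <- dend$merge[m, 2L]
    li <- if (l < 0L) -l else cluster_of_node[l]
    ri <- if (r < 0L) -r else cluster_of_node[r]
    li <- find(li); ri <- find(ri)
    if (dend$height[m] <= cutoff && li != ri) parent[ri] <- li
    cluster_of_node[m] <- find(li)
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  # number clusters by first appearance along the dendrogram leaf order
  first_seen <- unique(roots[dend$order])
  idx <- match(roots, first_seen)
  names(idx) <- dend$labels
  clusters <- split(dend$labels, idx)
  names(clusters) <- paste0("cluster", names(clusters))
  structure(list(cutoff = cutoff, assignment = idx, clusters = clusters),
            class = "tox_partition")
}

#' @export
print.tox_partition <- function(x, ...) {
  sizes <- vapply(x$clusters, length, integer(1L))
  cat(sprintf("tox_partition: cutoff %.4g -> %d cluster(s) [%s]\n",
              x$cutoff, length(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Cluster a group table (rows, columns, cutoff partition)
#'
#' Orchestrates distance computation, linkage and the optional cutoff for
#' the configured axes. Row clusters obtained from the cutoff are emitted
#' as gene sets named `cluster1..K`.
#'
#' @param table a [build_group_matrix()] result or plain numeric matrix.
#' @param config a [clustering_config()].
#' @param cutoff optional height cutoff for the row dendrogram.
#' @return An object of class `tox_clustering`: list with
#'   `row_dendrogram`, `col_dendrogram` (or NULL), `partition` (or NULL),
#'   `genesets` (list of [gene_set()]s, when a cutoff is given), `config`,
#'   `cutoff`.
#' @export
cluster_table <- function(table, config = clustering_config(),
                          cutoff = NULL) {
  stopifnot(inherits(config, "tox_clust_config"))
  values <- if (inherits(table, "tox_group_table")) table$values else table
  check_that(is.matrix(values) && nrow(values) >= 2L,
             "clustering needs a matrix with >= 2 rows")
  dist_of <- function(m) {
    if (config$distance == "pearson") pearson_distance_matrix(m)
    else as.matrix(dist(m))
  }
  row_dend <- col_dend <- partition <- NULL
  if (config$axis %in% c("rows", "both")) {
    if (nrow(values) > config$max_genes) {
      stop(sprintf(
        "size limit: clustering is limited to sets of %d genes or less (got %d)",
        config$max_genes, nrow(values)), call. = FALSE)
    }
    row_dend <- hierarchical_cluster(dist_of(values), config$method,
                                     max_genes = config$max_genes)
  }
  if (config$axis %in% c("columns", "both") && ncol(values) >= 2L) {
    col_dend <- hierarchical_cluster(dist_of(t(values)), config$method,
                                     max_genes = .Machine$integer.max)
  }
  genesets <- NULL
  if (!is.null(cutoff) && !is.null(row_dend)) {
    partition <- cut_dendrogram(row_dend, cutoff)
    genesets <- lapply(names(partition$clusters), function(nm)
      gene_set(nm, partition$clusters[[nm]],
               provenance = sprintf(
                 "cluster from %s/%s dendrogram at cutoff %s",
                 config$method, config$distance, format(cutoff))))
    names(genesets) <- names(partition$clusters)
  }
  structure(list(row_dendrogram = row_dend, col_dendrogram = col_dend,
                 partition = partition, genesets = genesets,
                 config = config, cutoff = cutoff),
            class = "tox_clustering")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expected value for independent
#' ones.
#'
#' @param a,b vectors of cluster labels for the same items (same length;
#'   if both are named, `b` is aligned to `a`'s names).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  check_that(length(a) == length(b), "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
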