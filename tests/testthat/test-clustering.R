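ref_method <- c(ward_d2 = "ward.D2", average = "average",
                complete = "complete", single = "single")

random_dend <- function(n, seed, method = "average") {
  set.seed(seed)
  x <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("p%03d", 1:n),
                                               NULL))
  hierarchical_cluster(as.matrix(dist(x)), method)
}

test_that("Pearson distance has the documented geometry", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 4, 6))
  d <- pearson_distance_matrix(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 2)      # r = -1
  expect_equal(d["a", "c"], 0)      # r = +1
  m2 <- rbind(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1))
  expect_equal(pearson_distance_matrix(m2)["x", "y"], 1) # r = 0
  mc <- rbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(pearson_distance_matrix(mc), "flat")
})

test_that("small dendrograms match hand enumeration", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (m in names(ref_method)) {
    dend <- hierarchical_cluster(d2, m)
    expect_equal(dend$height, 3)
  }
  # collinear points 0, 1, 2: single linkage merges at 1 then 1
  d3 <- as.matrix(dist(c(0, 1, 2)))
  dend3 <- hierarchical_cluster(d3, "single")
  expect_equal(dend3$height, c(1, 1))
})

test_that("dendrogram structure is well-formed", {
  dend <- random_dend(25, seed = 3, method = "ward_d2")
  expect_equal(nrow(dend$merge), 24)
  expect_equal(sort(dend$order), 1:25)
  # heights non-decreasing for monotone linkages
  expect_true(all(diff(dend$height) >= -1e-12))
  # every leaf appears exactly once in the merge matrix
  leaves <- -dend$merge[dend$merge < 0]
  expect_equal(sort(leaves), 1:25)
})

test_that("all four linkages match the reference implementation", {
  set.seed(29)
  for (i in 1:30) {
    x <- matrix(rnorm(20 * 5), 20)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- sprintf("p%02d", 1:20)
    for (m in names(ref_method)) {
      mine <- hierarchical_cluster(d, m)
      ref <- hclust(as.dist(d), method = ref_method[[m]])
      expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-8)
      # structure equivalence via cophenetic distances
      expect_equal(as.matrix(cophenetic(as.hclust(mine))),
                   as.matrix(cophenetic(ref)), tolerance = 1e-8)
    }
  }
})

test_that("cutting at the extremes gives one cluster / all singletons", {
  dend <- random_dend(12, seed = 5)
  all_in_one <- cut_dendrogram(dend, max(dend$height))
  expect_length(all_in_one$clusters, 1L)
  expect_setequal(all_in_one$clusters[[1]], dend$labels)
  shattered <- cut_dendrogram(dend, min(dend$height) - 1e-9)
  expect_length(shattered$clusters, 12L)
})

test_that("cluster count is monotone non-increasing in the cutoff", {
  for (seed in 1:5) {
    dend <- random_dend(15, seed = seed, method = "complete")
    cuts <- sort(runif(20, 0, max(dend$height) * 1.1))
    ks <- vapply(cuts, function(ct)
      length(cut_dendrogram(dend, ct)$clusters), integer(1L))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("cut partition equals the connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(37)
  dend <- random_dend(10, seed = 41)
  for (ct in runif(50, -0.1, max(dend$height) * 1.05)) {
    part <- cut_dendrogram(dend, ct)
    # oracle: join the two merged subtrees for every merge height<=cutoff
    g <- igraph::make_empty_graph(n = 10, directed = FALSE)
    members <- as.list(1:10)
    for (m in seq_len(9)) {
      l <- dend$merge[m, 1]; r <- dend$merge[m, 2]
      lm <- if (l < 0) -l else members[[10 + l]]
      rm <- if (r < 0) -r else members[[10 + r]]
      members[[10 + m]] <- c(lm, rm)
      if (dend$height[m] <= ct) {
        g <- igraph::add_edges(g, c(lm[1], rm[1]))
      }
    }
    comp <- igraph::components(g)$membership
    expect_equal(adjusted_rand_index(part$assignment,
                                     setNames(comp, dend$labels)), 1)
    expect_length(part$clusters, max(comp))
  }
})

test_that("cluster_table enforces the 1000-gene limit", {
  set.seed(43)
  ok <- matrix(rnorm(1000 * 4), 1000,
               dimnames = list(sprintf("p%04d", 1:1000), NULL))
  expect_silent(res <- cluster_table(ok, clustering_config(
    distance = "euclidean", axis = "rows")))
  too_big <- rbind(ok, p1001 = rnorm(4))
  expect_error(cluster_table(too_big, clustering_config(
    distance = "euclidean", axis = "rows")), "1000")
})

test_that("planted identical blocks are recovered exactly", {
  m <- rbind(matrix(rep(c(0, 1, 2, 3), each = 6), 6, byrow = FALSE),
             matrix(rep(c(3, 1, 0, 2), each = 6), 6, byrow = FALSE))
  m <- m + 0 # two blocks of 6 identical rows each
  rownames(m) <- sprintf("p%02d", 1:12)
  res <- cluster_table(m, clustering_config(distance = "euclidean",
                                            axis = "rows"), cutoff = 0.5)
  expect_length(res$partition$clusters, 2L)
  expect_setequal(res$partition$clusters[[1]], rownames(m)[1:6])
  expect_setequal(res$partition$clusters[[2]], rownames(m)[7:12])
  expect_named(res$genesets, c("cluster1", "cluster2"))
})

test_that("clustering is invariant under row permutation (up to labels)", {
  set.seed(47)
  m <- matrix(rnorm(30 * 5), 30, dimnames = list(sprintf("p%02d", 1:30),
                                                 NULL))
  res <- cluster_table(m, clustering_config(axis = "rows"), cutoff = 0.8)
  perm <- sample(30)
  res2 <- cluster_table(m[perm, ], clustering_config(axis = "rows"),
                        cutoff = 0.8)
  expect_equal(sort(res$row_dendrogram$height),
               sort(res2$row_dendrogram$height))
  expect_equal(adjusted_rand_index(res$partition$assignment,
                                   res2$partition$assignment), 1)
})

test_that("column dendrogram is built for axis = both", {
  set.seed(53)
  m <- matrix(rnorm(20 * 6), 20, dimnames = list(sprintf("p%02d", 1:20),
                                                 sprintf("g%d", 1:6)))
  res <- cluster_table(m, clustering_config(axis = "both"))
  expect_s3_class(res$col_dendrogram, "tox_dendrogram")
  expect_equal(res$col_dendrogram$n_leaves, 6L)
})

test_that("adjusted Rand index behaves", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(5, 5, 9, 9, 7)), 1) # relabeling
  # hand-computed small case: fully crossed 2x2 design
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
})
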