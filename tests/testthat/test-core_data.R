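test_that("median_normalize divides each column by its median", {
  m <- matrix(c(2, 4, 8), ncol = 1)
  expect_equal(unname(median_normalize(tiny_ds(m))$intensities[, 1]),
               c(0.5, 1, 2))
  expect_equal(unname(median_normalize(tiny_ds(matrix(5)))$intensities[, 1]),
               1)
  # even length: median is the mean of the two middle order statistics
  expect_equal(unname(median_normalize(
    tiny_ds(matrix(c(1, 3), ncol = 1)))$intensities[, 1]),
    c(0.5, 1.5))
})

test_that("column medians equal 1 after normalization (random matrices)", {
  set.seed(11)
  for (n in c(7, 10, 51)) {
    m <- matrix(rexp(n * 4) + 0.1, nrow = n)
    norm <- median_normalize(tiny_ds(m))
    expect_equal(unname(apply(norm$intensities, 2, median)), rep(1, 4))
  }
})

test_that("non-positive intensities are rejected naming probe and sample", {
  m <- matrix(c(1, 2, -1, 4), 2, dimnames = list(c("pA", "pB"),
                                                 c("s1", "s2")))
  expect_error(tiny_ds(m), "pA.*s2")
  m[1, 2] <- 0
  expect_error(tiny_ds(m), "non-positive")
})

test_that("dataset constructor validates structure", {
  m <- matrix(1:4 + 0.0, 2, dimnames = list(c("p1", "p1"), c("s1", "s2")))
  expect_error(tiny_ds(m), "duplicate probe")
  m2 <- matrix(1:4 + 0.0, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  meta <- tiny_meta(c("s1", "s1"), c("Control", "Control"))
  expect_error(tox_dataset(m2, meta), "duplicate sample")
  meta2 <- tiny_meta(c("s1", "s3"), c("Control", "Control"))
  expect_error(tox_dataset(m2, meta2), "sample sets differ")
  # control key must resolve to a Control-dose sample
  meta3 <- tiny_meta(c("s1", "s2"), c("Middle", "High"))
  expect_error(tox_dataset(m2, meta3), "no Control-dose sample")
  expect_error(tox_dataset(m2, tiny_meta(c("s1", "s2"),
                                         c("Control", "Low"))[, -3]),
               "missing required column")
})

test_that("compute_fold divides by the control mean", {
  ctrl <- matrix(c(2, 4), 1, dimnames = list("p1", NULL))
  expect_equal(unname(compute_fold(c(p1 = 6), ctrl)), 2)
  ctrl3 <- matrix(rep(2, 3), 1, dimnames = list("p1", NULL))
  expect_equal(unname(compute_fold(c(p1 = 2), ctrl3)), 1)
  ctrl2 <- matrix(c(4, 4), 1, dimnames = list("p1", NULL))
  expect_equal(unname(compute_fold(c(p1 = 1), ctrl2)), 0.25)
  expect_error(compute_fold(c(p1 = 1), ctrl[, 0, drop = FALSE]),
               "non-empty")
  expect_error(compute_fold(c(p2 = 1), ctrl), "mismatch")
})

test_that("group value is mean-then-log2, not mean-of-logs", {
  expect_equal(group_log2_value(c(2, 2)), 1)
  expect_equal(group_log2_value(c(1, 4)), log2(2.5)) # NOT (0 + 2)/2 = 1
  expect_equal(group_log2_value(0.5), -1)
  expect_error(group_log2_value(numeric()), "empty")
  expect_error(group_log2_value(c(1, -2)), "positive")
})

test_that("group value dominates mean of per-sample log2 folds (Jensen)", {
  set.seed(21)
  for (i in 1:50) {
    f <- rexp(sample(2:8, 1)) + 0.05
    expect_gte(group_log2_value(f), mean(log2(f)) - 1e-12)
  }
  expect_equal(group_log2_value(c(3, 3, 3)), mean(log2(c(3, 3, 3))))
})

test_that("build_group_matrix matches hand values", {
  ds <- treated_ds(ctrl = matrix(c(1, 1), 1), treated = matrix(c(2, 2), 1))
  tab <- build_group_matrix(ds, treated_group(ds))
  expect_equal(unname(tab$values[1, 1]), 1)
  # group identical to its control distribution: all folds 1 -> 0
  ds0 <- treated_ds(ctrl = matrix(c(4, 4), 1), treated = matrix(c(4, 4), 1))
  tab0 <- build_group_matrix(ds0, treated_group(ds0))
  expect_equal(unname(tab0$values[1, 1]), 0)
})

test_that("build_group_matrix equals the brute-force oracle", {
  set.seed(31)
  m <- matrix(rexp(50 * 15) + 0.1, nrow = 50)
  doses <- rep(c("Control", "Low", "Middle", "High"), c(6, 3, 3, 3))
  ds <- tiny_ds(m, doses)
  groups <- make_groups(ds)
  expect_length(groups, 3L)
  tab <- build_group_matrix(ds, groups)
  expect_equal(tab$values, oracle_group_matrix(ds, groups))
})

test_that("group table is invariant to sample and probe order", {
  set.seed(41)
  m <- matrix(rexp(20 * 8) + 0.1, nrow = 20)
  ds <- tiny_ds(m, rep(c("Control", "Middle"), each = 4))
  g <- treated_group(ds)
  tab <- build_group_matrix(ds, g)
  # permute samples within the group definition
  g2 <- sample_group(g$name, rev(g$sample_ids), rev(g$control_sample_ids))
  expect_equal(build_group_matrix(ds, g2)$values, tab$values)
  # permute probe rows of the dataset
  perm <- sample(nrow(m))
  ds2 <- tox_dataset(ds$intensities[perm, ], ds$samples)
  tab2 <- build_group_matrix(ds2, g)
  expect_equal(tab2$values[rownames(tab$values), , drop = FALSE],
               tab$values)
})

test_that("unknown sample IDs in groups are itemized", {
  ds <- treated_ds(matrix(c(1, 1), 1), matrix(c(2, 2), 1))
  g <- sample_group("bad", c("t1", "ghost"), "c1")
  expect_error(build_group_matrix(ds, g), "ghost")
})

test_that("absolute mode aggregates with the plain mean", {
  ds <- treated_ds(matrix(c(2, 4), 1), matrix(c(3, 5), 1))
  tab <- build_group_matrix(ds, treated_group(ds), mode = "absolute")
  expect_equal(unname(tab$values[1, 1]), 4)
})
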