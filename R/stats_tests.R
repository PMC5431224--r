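#' @name stat-tests
#' @title Statistical test columns: Welch's t and Mann-Whitney U
#'
#' @description
#' Differential-expression style test columns comparing two sample groups
#' probe by probe. Both tests are two-sided. Welch's t-test does not assume
#' equal variances and uses the Welch-Satterthwaite degrees of freedom; the
#' Mann-Whitney U test is exact (by enumeration of the rank-sum
#' distribution) for small tie-free samples and falls back to a
#' tie-corrected normal approximation otherwise. p-values are reported raw:
#' the filtering stage deliberately thresholds unadjusted p-values, and
#' multiplicity adjustment lives in the enrichment module.
NULL

#' Welch's two-sample t-test
#'
#' @param a,b numeric vectors with at least 2 observations each.
#' @return List with `statistic` (t, sign of `mean(a) - mean(b)`),
#'   `df` (Welch-Satterthwaite) and `p.value` (two-sided).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6)) # |t| ~ 3.674, df = 4
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  check_that(length(a) >= 2L && length(b) >= 2L,
             "Welch's t-test needs >= 2 observations per group")
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  check_that(se2 > 0, "Welch's t-test undefined: zero variance in both groups")
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

# row-wise Welch over matrices A (probes x nA) and B (probes x nB);
# probes where the test is undefined get NA (reported by the caller)
welch_t_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  va <- row_vars(A); vb <- row_vars(B)
  se2 <- va / na + vb / nb
  t <- (rowMeans(A) - rowMeans(B)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  bad <- !(se2 > 0)
  t[bad] <- NA_real_; df[bad] <- NA_real_; p[bad] <- NA_real_
  list(statistic = t, df = df, p.value = p)
}

# exact null distribution of the Mann-Whitney U statistic: counts of
# (m, n)-splits attaining each U value, by the standard recurrence
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1), rolling on n
dp_mwu <- function(m, n) {
  umax <- m * n
  # f[mm+1, u+1] for current nn
  f <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
  f[1L, 1L] <- 1          # nn = 0, mm = 0 (and mm > 0 has U = 0 too)
  f[, 1L] <- 1            # with no b-observations U is always 0
  for (nn in seq_len(n)) {
    g <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
    g[1L, 1L] <- 1        # mm = 0: U = 0 only
    for (mm in seq_len(m)) {
      # N(u; mm, nn) = N(u - nn; mm - 1, nn) + N(u; mm, nn - 1)
      shifted <- c(rep(0, nn), g[mm, seq_len(umax + 1L - nn)])
      g[mm + 1L, ] <- shifted + f[mm + 1L, ]
    }
    f <- g
  }
  f[m + 1L, ]
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs `(a_i, b_j)` with `a_i > b_j` (ties count 1/2).
#' For `length(a) + length(b) <= max_exact` with no ties the two-sided
#' p-value is exact: `min(1, 2 * min(P(U <= u), P(U >= u)))` under the
#' permutation distribution. Otherwise a normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param max_exact largest combined sample size for the exact path.
#' @return List with `statistic` (U for sample `a`), `p.value`, and
#'   `exact` (logical).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney <- function(a, b, max_exact = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  check_that(na >= 1L && nb >= 1L, "both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && na + nb <= max_exact) {
    counts <- dp_mwu(na, nb)
    total <- sum(counts)
    lo <- sum(counts[seq_len(u + 1L)]) / total        # P(U <= u)
    hi <- sum(counts[(u + 1L):length(counts)]) / total # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = u, p.value = p, exact = TRUE))
  }
  n <- na + nb
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1, exact = FALSE))
  z <- (u - na * nb / 2) / sqrt(sigma2)
  list(statistic = u, p.value = 2 * pnorm(-abs(z)), exact = FALSE)
}

#' Add a statistical test column comparing two groups
#'
#' Computes a probe-indexed p-value column for the comparison of two
#' sample groups, on per-sample log2 fold values (default) or on the
#' normalized intensities. Probes where a test is undefined (too few
#' replicates after NA removal, or zero variance in both groups for
#' Welch's t) are reported as `NA` with a warning, not as an error.
#'
#' @param dataset a [tox_dataset()].
#' @param group_a,group_b [sample_group()] objects to compare.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param values `"log2_fold"` (per-sample log2 folds against matched
#'   controls) or `"absolute"` (intensities).
#' @return An object of class `tox_stat_column`: list with `test`,
#'   `group_a`, `group_b`, probe-named `p.value` and `statistic` vectors.
#' @export
stat_column <- function(dataset, group_a, group_b,
                        test = c("welch_t", "mann_whitney"),
                        values = c("log2_fold", "absolute")) {
  stopifnot(inherits(dataset, "tox_dataset"),
            inherits(group_a, "tox_group"), inherits(group_b, "tox_group"))
  test <- match.arg(test)
  values <- match.arg(values)
  check_group_samples(dataset, list(group_a, group_b))
  get_vals <- function(g) {
    if (values == "log2_fold") {
      log2(fold_for_samples(dataset, g$sample_ids, g$control_sample_ids))
    } else {
      dataset$intensities[, g$sample_ids, drop = FALSE]
    }
  }
  A <- get_vals(group_a); B <- get_vals(group_b)
  if (test == "welch_t") {
    check_that(ncol(A) >= 2L && ncol(B) >= 2L,
               "Welch's t-test needs >= 2 samples per group")
    res <- welch_t_rows(A, B)
    p <- res$p.value; stat <- res$statistic
  } else {
    n <- nrow(A)
    p <- stat <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      r <- mann_whitney(A[i, ], B[i, ])
      p[i] <- r$p.value; stat[i] <- r$statistic
    }
  }
  names(p) <- names(stat) <- dataset$probes
  n_bad <- sum(is.na(p))
  if (n_bad > 0L)
    warning(sprintf("test undefined for %d probe(s); reported as NA", n_bad),
            call. = FALSE)
  structure(list(test = test, group_a = group_a$name,
                 group_b = group_b$name, values = values,
                 p.value = p, statistic = stat),
            class = "tox_stat_column")
}
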