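# fixtures are built in code: small handcrafted datasets plus oracles
# used by the DERIVED-value tests

# metadata for one compound/organ/time block, doses as given
tiny_meta <- function(ids, doses, compound = "cpdA", time = "4 day",
                      organ = "liver", platform = "Rat230_2") {
  data.frame(sample_id = ids, compound = compound, dose_level = doses,
             exposure_time = time, organ = organ, species = "rat",
             platform = platform, test_type = "in_vivo",
             control_group = paste(compound, organ, time, sep = "|"),
             stringsAsFactors = FALSE)
}

# dataset from an intensity matrix; doses default to Control for all
tiny_ds <- function(m, doses = rep("Control", ncol(m)), ...) {
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tox_dataset(m, tiny_meta(colnames(m), doses, ...))
}

# canonical 2-control + k-treated fixture on given intensities
treated_ds <- function(ctrl, treated, ...) {
  m <- cbind(ctrl, treated)
  colnames(m) <- c(paste0("c", seq_len(ncol(ctrl))),
                   paste0("t", seq_len(ncol(treated))))
  tiny_ds(m, c(rep("Control", ncol(ctrl)), rep("Middle", ncol(treated))),
          ...)
}

treated_group <- function(ds, name = "g1") {
  s <- ds$samples
  sample_group(name, s$sample_id[s$dose_level != "Control"],
               s$sample_id[s$dose_level == "Control"],
               factors = list(compound = s$compound[1L],
                              dose_level = "Middle",
                              exposure_time = s$exposure_time[1L]))
}

# --- oracles -----------------------------------------------------------

# brute-force mean-then-log2 recomputation of the group table
oracle_group_matrix <- function(ds, groups) {
  out <- matrix(NA_real_, length(ds$probes), length(groups),
                dimnames = list(ds$probes, names(groups)))
  for (g in seq_along(groups)) {
    gr <- groups[[g]]
    for (p in seq_along(ds$probes)) {
      ctrl <- mean(ds$intensities[p, gr$control_sample_ids])
      folds <- ds$intensities[p, gr$sample_ids] / ctrl
      out[p, g] <- log2(mean(folds))
    }
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating every labeling of the
# pooled values (independent of the package's DP route)
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(combn(length(pooled), na), 2L, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# exhaustive hypergeometric tail: overlap distribution of an n-subset of
# 1..N with the category 1..K, by enumerating all subsets
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  overlaps <- apply(combn(N, n), 2L, function(s) sum(s <= K))
  mean(overlaps >= k)
}
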