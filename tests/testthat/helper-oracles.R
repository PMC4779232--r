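# Shared fixtures and independent scalar oracles for the test suite.
# The oracles deliberately use per-gene loops, base order()/rank() and
# stats::t.test so they share no code path with the vectorized package
# internals they check.

# Small deterministic log2-difference dataset: G genes x (pairs_per_period * T)
# pairs in one or more strata.
make_dataset <- function(n_genes = 50, strata = "S1", pairs_per_period = 10,
                         n_periods = 3, seed = 1, delta = 0, n_signal = 0,
                         signal_labels = "123", noise_sd = 1) {
  cfg <- simulation_config(
    n_genes,
    uniform_design(strata, n_periods, pairs_per_period),
    n_signal = n_signal, signal_labels = signal_labels,
    delta = delta, noise_sd = noise_sd, seed = seed)
  generate_dataset(cfg)
}

# Scalar re-implementation of curve-group assignment under criterion 1.
oracle_assign <- function(x, ann, stratum, alpha = 0.01) {
  ann_s <- ann[ann$stratum == stratum, , drop = FALSE]
  periods <- sort(unique(ann$time_period))
  out <- data.frame(gene_id = rownames(x), label = NA_character_,
                    p_value = NA_real_, member = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    vals <- lapply(periods, function(t)
      x[i, ann_s$pair_id[ann_s$time_period == t]])
    means <- vapply(vals, mean, numeric(1))
    desc <- rev(means) # farthest -> nearest
    if (anyDuplicated(desc)) next
    out$label[i] <- paste(rank(desc), collapse = "")
    a <- vals[[which.min(means)]]
    b <- vals[[which.max(means)]]
    out$p_value[i] <- stats::t.test(a, b, var.equal = FALSE)$p.value
    out$member[i] <- out$p_value[i] < alpha
  }
  out
}

# Scalar Welch two-sample t-statistic (first minus second group).
oracle_tstat <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = FALSE)$statistic)
}

# Reference quantile normalization of a tie-free matrix via repeated scalar
# sorting (no shared code with the package implementation).
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}
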