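# Shared fixtures, built in code.

# Small, fast default cohort used across tests.
small_cohort <- function(seed = 7, ...) {
  generate_cohort(synth_config(n_samples = 72, n_genes = 300,
                               n_markers_per_subtype = 25, seed = seed, ...))
}

# Two raw-scale cohorts with backgrounds for probe-filter tests.
raw_cohort <- function(values, background, cohort = "c1", genes = NULL) {
  expression_matrix(values, gene_symbols = genes, cohort = cohort,
                    background = background, log_scale = FALSE)
}

allocate_counts_for_test <- function(n, cfg) {
  bonemet:::allocate_counts(n, cfg$subtype_proportions)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits.
exact_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
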