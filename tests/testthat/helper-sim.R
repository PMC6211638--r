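library(data.table)

# Small end-to-end dataset used by several tests.
tiny_dataset <- function(n_snps = 300, seed = 42, ...) {
  cfg <- sim_config(n_snps = n_snps, seed = seed, ...)
  d <- simulate_design(cfg)
  list(cfg = cfg, design = d$design, truth = d$truth,
       dna = simulate_dna_counts(d$design, d$truth, cfg),
       rna = simulate_rna_counts(d$design, d$truth, cfg))
}

# Binding simulation with region effects switched off (pure allelic layer).
flat_binding_config <- function(n_snps, seed, ...) {
  sim_config(n_snps = n_snps, frac_footprint = 0, region_logfc_mean_fp = 0,
             region_logfc_mean_bg = 0, region_logfc_sd = 0,
             region_nonspecific = c(low = 0, mid = 0, high = 0),
             seed = seed, ...)
}

# Naive BH step-up used as the independent multiple-testing oracle.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p down
  q[o] <- rev(cummin(rev(q[o])))
  pmin(q, 1)
}
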