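test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(rho_true = 0.6), "rho_true")
  expect_error(sim_config(rho_true = -0.1), "rho_true")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(pi_functional = 1.2), "pi_functional")
  expect_error(sim_config(dna_depth_mean = 0), "dna_depth_mean")
  expect_error(sim_config(conc_scale = c(1, 1)), "conc_scale")
  expect_error(sim_config(direction_factor = "NOPE"), "direction_factor")
})

test_that("design generation is deterministic and structurally sound", {
  cfg <- sim_config(n_snps = 500, seed = 9)
  d1 <- simulate_design(cfg)
  d2 <- simulate_design(cfg)
  expect_identical(d1, d2)

  expect_equal(nrow(d1$design), 500)
  expect_true(all(d1$design$ref_allele != d1$design$alt_allele))
  expect_true(all(d1$design$category %in%
                    c("eQTL", "CentiSNP", "GWAS", "negative_control")))
  # negative controls are guaranteed effect-free
  nc <- d1$truth[d1$design$category == "negative_control"]
  expect_true(all(nc$beta_true == 0))
  expect_true(all(nc$gamma_true == 0))
  expect_true(all(d1$truth$p_dna_true > 0 & d1$truth$p_dna_true < 1))
})

test_that("functional fraction behaves: forced null and seeded regression", {
  d0 <- simulate_design(sim_config(n_snps = 100, pi_functional = 0, seed = 1))
  expect_true(all(d0$truth$beta_true == 0))

  # Binomial(1000, 0.2) draw under seed 7; frozen by regenerating at this seed
  d <- simulate_design(sim_config(n_snps = 1000, pi_functional = 0.2, seed = 7))
  expect_identical(sum(d$truth$beta_true != 0), 214L)
})

test_that("DNA counts: symmetric-Beta limit, Poisson limit, determinism", {
  cfg <- sim_config(n_snps = 2000, lib_imbalance_conc = 1e8, nb_size = Inf,
                    dna_depth_mean = 100, n_dna_reps = 2, seed = 3)
  d <- simulate_design(cfg)
  expect_lt(max(abs(d$truth$p_dna_true - 0.5)), 0.001)

  dna <- simulate_dna_counts(d$design, d$truth, cfg)
  expect_identical(dna, simulate_dna_counts(d$design, d$truth, cfg))

  # totals per SNP per replicate are Poisson(100) in the nb_size -> Inf limit
  tot <- aggregate_counts(dna)[, ref_count + alt_count]
  se <- sqrt(100 / length(tot))
  expect_lt(abs(mean(tot) - 100), 3 * se)
})

test_that("RNA counts: null proportions track the library, effects shift them", {
  cfg <- sim_config(n_snps = 500, pi_functional = 0, rho_true = 0,
                    rna_depth_mean = 200, n_rna_reps = 5, seed = 4)
  d <- simulate_design(cfg)
  rna <- aggregate_counts(simulate_rna_counts(d$design, d$truth, cfg),
                          pool_replicates = TRUE)
  m <- merge(rna, d$truth, by = "snp_id")
  # pooled ref fraction converges to p_dna_true: aggregate z-score
  m[, `:=`(N = ref_count + alt_count)]
  dev <- m[, sum(ref_count - N * p_dna_true) /
               sqrt(sum(N * p_dna_true * (1 - p_dna_true)))]
  expect_lt(abs(dev), 3)

  # beta_true = +1 on p0 = 0.5 shifts the expected ref fraction to expit(1)
  cfg2 <- sim_config(n_snps = 400, pi_functional = 0, rho_true = 0,
                     lib_imbalance_conc = 1e9, rna_depth_mean = 500,
                     n_rna_reps = 2, seed = 5)
  d2 <- simulate_design(cfg2)
  d2$truth[, c("beta_true", "beta_fwd", "beta_rev") := 1]
  rna2 <- aggregate_counts(simulate_rna_counts(d2$design, d2$truth, cfg2),
                           pool_replicates = TRUE)
  frac <- rna2[, sum(ref_count) / sum(ref_count + alt_count)]
  n_tot <- rna2[, sum(ref_count + alt_count)]
  p1 <- plogis(1)
  expect_lt(abs(frac - p1), 3 * sqrt(p1 * (1 - p1) / n_tot))
})

test_that("molecule records expand counts exactly and stay deterministic", {
  cfg <- sim_config(n_snps = 80, rna_depth_mean = 40, mu_dup = 0,
                    umi_length = 12, n_rna_reps = 3, seed = 6)
  d <- simulate_design(cfg)
  cnt <- simulate_rna_counts(d$design, d$truth, cfg)
  mol <- simulate_rna_molecules(d$design, d$truth, cfg)
  # mu_dup = 0: one read per molecule
  expect_identical(nrow(mol), cnt[, sum(ref_count + alt_count)])

  # replicate-by-replicate generation slices identically to the full run
  mol_r2 <- simulate_rna_molecules(d$design, d$truth, cfg, replicates = 2L)
  expect_identical(mol_r2, mol[replicate == 2L][, .SD])

  # per-group read totals match the drawn molecule counts
  regrouped <- count_reads(mol)
  expect_identical(
    aggregate_counts(regrouped, pool_orientation = FALSE)[order(snp_id, orientation, replicate),
                                                          .(snp_id, orientation, replicate, ref_count, alt_count)],
    cnt[ref_count + alt_count > 0][order(snp_id, orientation, replicate),
                                   .(snp_id, orientation, replicate, ref_count, alt_count)]
  )
})

test_that("binding counts: null symmetry and footprint occupancy scaling", {
  cfg <- flat_binding_config(800, seed = 8, pi_asb = 0, pi_functional = 0,
                             fraction_depth_mean = 200, rho_true = 0)
  d <- simulate_design(cfg)
  b <- simulate_binding_counts(d$design, d$truth, cfg)
  ag <- b$allele[, .(p = sum(ref_count) / sum(ref_count + alt_count),
                     N = sum(ref_count + alt_count)), by = fraction]
  # gamma = 0: bound and unbound allele proportions identical in expectation
  expect_lt(abs(ag[fraction == "bound", p] - ag[fraction == "unbound", p]),
            3 * sqrt(0.25 / ag[, min(N)] * 2))

  cfg2 <- sim_config(n_snps = 2000, frac_footprint = 0.3,
                     region_logfc_mean_fp = 2, region_logfc_mean_bg = 0,
                     region_nonspecific = c(low = 0, mid = 0, high = 0),
                     pi_asb = 0, pi_functional = 0, seed = 9)
  d2 <- simulate_design(cfg2)
  b2 <- simulate_binding_counts(d2$design, d2$truth, cfg2)
  w <- dcast(b2$region[concentration == "mid"],
             region_id + replicate ~ fraction, value.var = "count")
  w <- merge(w, data.table(region_id = d2$design$region_id,
                           fp = d2$design$has_target_footprint),
             by = "region_id")
  lfc <- w[fp == TRUE & bound > 0 & unbound > 0, log2(bound / unbound)]
  expect_lt(abs(mean(lfc) - 2), 3 * sd(lfc) / sqrt(length(lfc)))
})

test_that("full dataset simulation is reproducible end to end", {
  cfg <- sim_config(n_snps = 60, seed = 10)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})
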