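test_that("Fisher enrichment matches hand-checked tables", {
  t1 <- fisher_table(10, 10, 10, 10)
  expect_equal(t1$odds_ratio, 1)
  expect_equal(t1$pvalue, 1)

  # perfect separation: p = 2 / C(10, 5)
  t2 <- fisher_table(5, 0, 0, 5)
  expect_equal(t2$pvalue, 2 / choose(10, 5))
  expect_identical(t2$odds_ratio, Inf)
  expect_identical(t2$ci95_high, Inf)

  expect_error(fisher_table(-1, 0, 0, 1), "non-negative")
  expect_error(fisher_table(0, 0, 0, 0), "empty")
})

test_that("Fisher p and conditional-MLE OR agree with enumeration oracles on
           small tables", {
  set.seed(61)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(5:25, 1), runif(4, 0.1, 1)))
    ft <- fisher_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ft$pvalue,
                 hypergeom_pvalue(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    or_o <- cmle_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    if (!is.nan(or_o) && is.finite(or_o) && or_o > 0 &&
        is.finite(ft$odds_ratio) && ft$odds_ratio > 0) {
      expect_equal(log(ft$odds_ratio), log(or_o), tolerance = 1e-2)
    }
  }
})

test_that("enrichment is invariant under simultaneous row/column relabeling
           and respects the universe contract", {
  uni <- sprintf("s%03d", 1:100)
  sig <- uni[1:30]
  ann <- uni[c(1:20, 51:60)]
  e1 <- fisher_enrichment(sig, ann, uni)
  # swap both: significant <-> not, annotated <-> not
  e2 <- fisher_enrichment(setdiff(uni, sig), setdiff(uni, ann), uni)
  expect_equal(e1$odds_ratio, e2$odds_ratio)
  expect_equal(e1$pvalue, e2$pvalue)

  expect_error(fisher_enrichment("zzz", ann, uni), "subset")
  expect_error(fisher_enrichment(sig, "zzz", uni), "subset")
  expect_error(fisher_enrichment(sig, ann, character(0)), "universe")
})

test_that("universe restriction changes the answer under testability bias", {
  # annotated SNPs are preferentially testable in both assays and
  # preferentially significant
  set.seed(62)
  uni_full <- sprintf("s%04d", 1:4000)
  ann <- uni_full[runif(4000) < 0.3]
  testable <- union(sample(uni_full, 2000),
                    sample(ann, 600)) # annotation-biased testability
  sig <- sample(testable, 300)
  e_tested <- fisher_enrichment(sig, intersect(ann, testable), testable)
  e_full <- fisher_enrichment(sig, ann, uni_full)
  expect_gt(abs(log(e_full$odds_ratio) - log(e_tested$odds_ratio)), 0.1)
})

test_that("overlap enrichment reports direction and overlap size", {
  uni <- sprintf("s%03d", 1:200)
  disjoint <- overlap_ase_asb(uni[1:40], uni[41:80], uni)
  expect_lt(disjoint$odds_ratio, 1)
  expect_identical(disjoint$n_overlap, 0L)

  same <- overlap_ase_asb(uni[1:40], uni[1:40], uni)
  expect_identical(same$odds_ratio, Inf)
  expect_identical(same$n_overlap, 40L)
})

test_that("correlated ASE and ASB effects produce overlap enrichment", {
  cfg <- flat_binding_config(4000, seed = 63, pi_functional = 0.25,
                             pi_asb = 0.25, effect_corr = 0.5,
                             rna_depth_mean = 200, dna_depth_mean = 200,
                             fraction_depth_mean = 200, tau_beta = 0.8,
                             tau_gamma = 0.8)
  d <- simulate_design(cfg)
  ase <- run_ase_pipeline(simulate_rna_counts(d$design, d$truth, cfg),
                          simulate_dna_counts(d$design, d$truth, cfg))
  asb <- run_asb_pipeline(simulate_binding_counts(d$design, d$truth, cfg)$allele)
  uni <- intersect(ase$meta$snp_id, asb$asb$overall$snp_id)
  ov <- overlap_ase_asb(ase$meta[significant == TRUE, snp_id],
                        asb$asb$overall[significant == TRUE, snp_id], uni)
  expect_gt(ov$odds_ratio, 1)
  expect_lt(ov$pvalue, 0.05)
})

test_that("direction configuration convention and degenerate margins", {
  expect_identical(direction_configuration(c("fwd", "fwd", "rev", "rev"),
                                           c("+", "-", "+", "-")),
                   c("match", "opposite", "opposite", "match"))
  expect_identical(direction_configuration("fwd", NA_character_),
                   NA_character_)

  # all oligos in one configuration: factor skipped with a warning
  res <- data.table(snp_id = c("a", "b", "c"), orientation = "fwd",
                    significant = c(TRUE, FALSE, TRUE))
  des <- data.table(snp_id = c("a", "b", "c"), motif_factor = "FOO",
                    motif_strand = "+")
  expect_warning(out <- direction_analysis(res, des), "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("permuted motif strands are not flagged by the direction analysis", {
  cfg <- sim_config(n_snps = 1200, pi_functional = 0.2,
                    direction_factor = "CTCF", rna_depth_mean = 200,
                    dna_depth_mean = 200, seed = 64)
  d <- simulate_design(cfg)
  dp <- estimate_dna_proportion(simulate_dna_counts(d$design, d$truth, cfg))
  rna <- simulate_rna_counts(d$design, d$truth, cfg)
  rho <- estimate_overdispersion(aggregate_counts(rna), dp)
  meta <- call_significant(
    fixed_effects(test_ase(rna, dp, rho), by = c("snp_id", "orientation")))
  real <- direction_analysis(meta, d$design)
  expect_true(real[annotation == "CTCF", flagged])

  set.seed(65)
  clean <- 0L
  for (i in 1:20) {
    perm <- copy(d$design)[, motif_strand := sample(motif_strand)]
    pa <- direction_analysis(meta, perm)
    clean <- clean + as.integer(sum(pa$flagged) == 0L)
  }
  expect_gte(clean, 19L)
})
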