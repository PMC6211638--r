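test_that("size factors recover depth multipliers", {
  set.seed(51)
  a <- rnbinom(400, size = 10, mu = 100) + 1L
  # sample 2 is exactly twice sample 1: factors proportional to (1, 2)
  sf <- size_factors(cbind(a, 2L * a))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)

  same <- cbind(a, a, a)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # random NB matrix with known depth multipliers
  mult <- c(0.5, 1, 1.5, 2, 3)
  mu <- rnbinom(600, size = 5, mu = 200) + 1
  m <- sapply(mult, function(s) rnbinom(600, size = 20, mu = mu * s))
  sf2 <- size_factors(m)
  sf2 <- sf2 / exp(mean(log(sf2)))
  mult_n <- mult / exp(mean(log(mult)))
  expect_lt(max(abs(sf2 / mult_n - 1)), 0.05)

  expect_error(size_factors(matrix(1:4, ncol = 1)), "2 samples")
  expect_warning(size_factors(rbind(c(5L, 0L), c(0L, 7L))), "total-count")
})

test_that("region test: label swap negates log2fc; joint gate enforced", {
  cfg <- flat_binding_config(300, seed = 52, pi_asb = 0, pi_functional = 0,
                             fraction_depth_mean = 200)
  cfg$frac_footprint <- 0.2
  cfg$region_logfc_mean_fp <- 2
  d <- simulate_design(cfg)
  b <- simulate_binding_counts(d$design, d$truth, cfg)
  rc <- b$region[concentration == "mid"]
  r1 <- region_test(rc)
  swapped <- copy(rc)[, fraction := ifelse(fraction == "bound",
                                           "unbound", "bound")]
  r2 <- region_test(swapped)
  m <- merge(r1, r2, by = "region_id", suffixes = c("_a", "_b"))
  expect_equal(m$log2fc_a, -m$log2fc_b, tolerance = 1e-9)

  # gate is joint: no call without both log2fc > 1 and q < 0.01
  expect_identical(r1$bound_call, r1$log2fc > 1 & r1$qvalue < 0.01)
})

test_that("sub-threshold fold changes are not called even when significant", {
  # deep, low-dispersion design so the lfc = 0.8 estimate is far from both 0
  # and the gate at 1: highly significant yet never called
  set.seed(53)
  n <- 200
  reps <- 10
  mu_b <- c(rep(5000 * 2^0.8, 20), rep(5000, 180)) # 10% spiked at lfc 0.8
  counts <- rbind(
    data.table(region_id = sprintf("r%03d", 1:n), fraction = "unbound",
               replicate = rep(seq_len(reps), each = n),
               count = rnbinom(reps * n, size = 400, mu = 5000)),
    data.table(region_id = sprintf("r%03d", 1:n), fraction = "bound",
               replicate = rep(seq_len(reps), each = n),
               count = rnbinom(reps * n, size = 400, mu = rep(mu_b, reps)))
  )
  r2 <- region_test(counts)
  spiked <- r2[region_id %in% sprintf("r%03d", 1:20)]
  expect_gt(sum(spiked$qvalue < 0.01), 15) # clearly significant
  expect_identical(sum(spiked$bound_call), 0L) # but gated out by logFC
})

test_that("control-set size-factor refinement removes composition bias under
           asymmetric enrichment", {
  cfg <- flat_binding_config(800, seed = 56, pi_asb = 0, pi_functional = 0,
                             fraction_depth_mean = 200)
  cfg$frac_footprint <- 0.2
  cfg$region_logfc_mean_fp <- 2
  d <- simulate_design(cfg)
  b <- simulate_binding_counts(d$design, d$truth, cfg)
  rc <- b$region[concentration == "mid"]
  truth_lfc <- data.table(region_id = d$design$region_id,
                          lfc = d$truth$region_logfc_true)
  med_lfc <- function(refine) {
    r <- region_test(rc, refine_size_factors = refine)
    merge(r, truth_lfc, by = "region_id")[lfc == 2, median(log2fc)]
  }
  plain <- med_lfc(FALSE)
  refined <- med_lfc(TRUE)
  expect_lt(plain, 1.9)            # median-of-ratios absorbs enrichment
  expect_gt(refined, plain + 0.1)  # control-set refinement restores it
  expect_lt(abs(refined - 2), 0.15)
})

test_that("footprint regions with elevated occupancy are enriched among
           calls", {
  cfg <- sim_config(n_snps = 800, frac_footprint = 0.2,
                    region_logfc_mean_fp = 2, region_logfc_mean_bg = 0,
                    region_logfc_sd = 0.5,
                    region_nonspecific = c(low = 0, mid = 0, high = 0),
                    fraction_depth_mean = 200, pi_asb = 0, pi_functional = 0,
                    seed = 54)
  d <- simulate_design(cfg)
  b <- simulate_binding_counts(d$design, d$truth, cfg)
  r <- region_test(b$region[concentration == "mid"])
  m <- merge(r, d$design[, .(region_id, has_target_footprint)],
             by = "region_id")
  er <- fisher_enrichment(m[bound_call == TRUE, region_id],
                          m[has_target_footprint == TRUE, region_id],
                          m$region_id, name = "footprint")
  expect_gt(er$odds_ratio, 1)
  expect_lt(er$pvalue, 0.01)
})

test_that("log2 fold changes track an independent negative-binomial
           reference implementation", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_snps = 300, frac_footprint = 0.2,
                    region_logfc_mean_fp = 2, region_logfc_sd = 0.5,
                    region_nonspecific = c(low = 0, mid = 0, high = 0),
                    fraction_depth_mean = 200, pi_asb = 0, pi_functional = 0,
                    seed = 55)
  d <- simulate_design(cfg)
  b <- simulate_binding_counts(d$design, d$truth, cfg)
  rc <- b$region[concentration == "mid"]
  ours <- region_test(rc)

  wide <- dcast(rc, region_id ~ fraction + replicate, value.var = "count")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$region_id
  cond <- factor(sub("_[0-9]+$", "", colnames(mat)),
                 levels = c("unbound", "bound"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    mat, S4Vectors::DataFrame(condition = cond), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  m <- merge(ours, data.table(region_id = rownames(ref),
                              lfc_ref = ref$log2FoldChange), by = "region_id")
  expect_gt(stats::cor(m$log2fc, m$lfc_ref), 0.95)
})
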