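# Canned simulation experiments: each function freezes one study condition
# (null calibration, duplicate ablation, effect recovery, binding robustness,
# region gate, enrichment recovery) and measures the pipeline's operating
# characteristics on data generated under it. Shared by the test suite, the
# analysis drivers and scripts/acceptance.R so every reported number comes
# from one code path.

#' Null calibration of the allelic-imbalance test
#'
#' Simulates SNPs with no true effects (pi_functional = 0), runs the full
#' ASE pipeline (overdispersion estimated from the same data), and measures
#' the empirical type-I error at `alpha` and the genomic inflation factor,
#' both per replicate and after fixed-effects meta-analysis.
#'
#' @param n_snps number of null SNPs (default 10,000).
#' @param rho_true generator overdispersion (default 0.02).
#' @param depth molecules per SNP per replicate (default 100).
#' @param n_reps RNA replicates (default 3).
#' @param alpha nominal level (default 0.05).
#' @param seed RNG seed.
#' @return list: `type1_per_replicate`, `type1_meta`, `lambda_per_replicate`,
#'   `lambda_meta`, `rho_hat`, `n_snps`.
#' @export
experiment_ase_calibration <- function(n_snps = 10000, rho_true = 0.02,
                                       depth = 100, n_reps = 3,
                                       alpha = 0.05, seed = 1) {
  cfg <- sim_config(n_snps = n_snps, pi_functional = 0, pi_asb = 0,
                    rho_true = rho_true, rna_depth_mean = depth,
                    dna_depth_mean = depth, n_rna_reps = n_reps, seed = seed)
  d <- simulate_design(cfg)
  res <- run_ase_pipeline(simulate_rna_counts(d$design, d$truth, cfg),
                          simulate_dna_counts(d$design, d$truth, cfg))
  list(
    type1_per_replicate = mean(res$per_replicate$pvalue < alpha),
    type1_meta = mean(res$meta$pvalue < alpha),
    lambda_per_replicate = genomic_inflation(res$per_replicate$pvalue)$lambda_gc,
    lambda_meta = res$inflation$lambda_gc,
    rho_hat = res$rho$rho,
    n_snps = nrow(res$meta)
  )
}

#' PCR-duplicate ablation: inflation with and without UMI collapse
#'
#' Simulates UMI-tagged reads with PCR duplication (`mu_dup`), runs the ASE
#' pipeline twice — collapsing duplicates by UMI versus counting raw reads —
#' and compares genomic inflation. The duplicate-retaining arm reuses the
#' molecule-level overdispersion estimate, isolating the effect of counting
#' reads as if they were molecules. Also counts FDR < `fdr` discoveries from
#' the meta-analysis of all replicates versus each single replicate.
#'
#' @param n_snps SNPs (default 10,000); `pi_functional` defaults to the
#'   generator's 0.2 so discovery counts are meaningful.
#' @param mu_dup mean extra PCR copies per molecule (default 3).
#' @param depth molecules per SNP per replicate (default 100).
#' @param n_reps RNA replicates (default 9).
#' @param fdr discovery threshold (default 0.10).
#' @param seed RNG seed.
#' @return list: `lambda_dedup`, `lambda_no_dedup`, `discoveries_meta`,
#'   `discoveries_single` (per-replicate vector), `n_snps`, `n_reads`.
#' @export
experiment_umi_inflation <- function(n_snps = 10000, mu_dup = 3, depth = 100,
                                     n_reps = 9, fdr = 0.10, seed = 1) {
  cfg <- sim_config(n_snps = n_snps, rho_true = 0.02, mu_dup = mu_dup,
                    rna_depth_mean = depth, dna_depth_mean = depth,
                    n_rna_reps = n_reps, seed = seed)
  d <- simulate_design(cfg)
  dna <- simulate_dna_counts(d$design, d$truth, cfg)
  mol <- simulate_rna_molecules(d$design, d$truth, cfg)
  arm_dedup <- run_ase_pipeline(mol, dna, dedup = TRUE, fdr = fdr)
  arm_raw <- run_ase_pipeline(mol, dna, dedup = FALSE, rho = arm_dedup$rho,
                              fdr = fdr)
  singles <- arm_dedup$per_replicate[
    , .(n = sum(adjust_pvalues(pvalue) < fdr)), by = replicate]
  list(
    lambda_dedup = arm_dedup$inflation$lambda_gc,
    lambda_no_dedup = arm_raw$inflation$lambda_gc,
    discoveries_meta = attr(arm_dedup$meta, "n_significant"),
    discoveries_single = singles$n,
    n_snps = nrow(arm_dedup$meta),
    n_reads = nrow(mol)
  )
}

#' Effect-size and overdispersion recovery
#'
#' Simulates a mixture of null and functional SNPs (effects
#' `beta_true ~ N(0, tau_beta^2)`), runs the ASE pipeline, and reports the
#' Pearson correlation between the meta-analytic effect estimate and the
#' truth — over all SNPs and over the functional subset — plus the
#' overdispersion estimate.
#'
#' @param n_snps SNPs (default 5,000).
#' @param pi_functional functional fraction (default 0.2).
#' @param tau_beta effect SD (default 0.5).
#' @param rho_true generator overdispersion (default 0.05).
#' @param depth molecules per SNP per replicate (default 200).
#' @param n_reps RNA replicates (default 9).
#' @param seed RNG seed.
#' @return list: `cor_all`, `cor_functional`, `rho_hat`, `n_snps`.
#' @export
experiment_effect_recovery <- function(n_snps = 5000, pi_functional = 0.2,
                                       tau_beta = 0.5, rho_true = 0.05,
                                       depth = 200, n_reps = 9, seed = 1) {
  cfg <- sim_config(n_snps = n_snps, pi_functional = pi_functional,
                    tau_beta = tau_beta, rho_true = rho_true,
                    rna_depth_mean = depth, dna_depth_mean = depth,
                    n_rna_reps = n_reps, seed = seed)
  d <- simulate_design(cfg)
  res <- run_ase_pipeline(simulate_rna_counts(d$design, d$truth, cfg),
                          simulate_dna_counts(d$design, d$truth, cfg))
  m <- merge(res$meta, d$truth, by = "snp_id")
  list(
    cor_all = m[, stats::cor(beta_meta, beta_true)],
    cor_functional = m[beta_true != 0, stats::cor(beta_meta, beta_true)],
    rho_hat = res$rho$rho,
    n_snps = nrow(m)
  )
}

#' Delta-AST robustness and power under library imbalance
#'
#' Two simulations sharing the binding-assay replicate structure (bound and
#' unbound fractions, triplicate at three concentrations):
#'
#' 1. *null*: no binding effects, strongly skewed plasmid library
#'    (`Beta(skew_conc, skew_conc)` reference proportions). Measures
#'    delta-AST type-I error at `alpha` — the shared imbalance must cancel —
#'    and, for contrast, the inflation of a naive bound-only test that
#'    assumes a balanced library.
#' 2. *power*: a fraction `pi_asb` of SNPs get binding effects of exactly
#'    `|gamma| = 1` (random sign) at `depth` molecules. Measures the sign
#'    agreement of the overall combined Z with the true effect and the
#'    per-concentration FDR < `fdr` discovery counts.
#'
#' @param n_snps SNPs per simulation (default 5,000).
#' @param skew_conc library imbalance Beta concentration for the null arm
#'   (default 5).
#' @param null_depth,depth fraction depths for the two arms (defaults 100 and
#'   200).
#' @param pi_asb fraction with `|gamma| = 1` in the power arm (default 0.2).
#' @param alpha nominal level (default 0.05).
#' @param fdr discovery threshold (default 0.10).
#' @param seed RNG seed.
#' @return list: `type1_dast`, `lambda_naive_bound_only`, `sign_agreement`,
#'   `discoveries` (named per concentration), `n_snps`.
#' @export
experiment_dast <- function(n_snps = 5000, skew_conc = 5, null_depth = 100,
                            depth = 200, pi_asb = 0.2, alpha = 0.05,
                            fdr = 0.10, seed = 1) {
  flat <- c(low = 0, mid = 0, high = 0)
  cfg0 <- sim_config(n_snps = n_snps, pi_functional = 0, pi_asb = 0,
                     lib_imbalance_conc = skew_conc,
                     fraction_depth_mean = null_depth,
                     frac_footprint = 0, region_logfc_mean_fp = 0,
                     region_logfc_sd = 0, region_nonspecific = flat,
                     seed = seed)
  d0 <- simulate_design(cfg0)
  b0 <- simulate_binding_counts(d0$design, d0$truth, cfg0)
  r0 <- run_asb_pipeline(b0$allele)
  # naive contrast: bound fraction tested against an assumed balanced library
  naive_dna <- data.table(snp_id = d0$design$snp_id, p0 = 0.5,
                          var0 = 1e-12, d_total = NA_integer_)
  naive <- test_ase(b0$allele[fraction == "bound"], naive_dna,
                    rho = r0$rho_table[fraction == "bound"][, .(concentration, rho)],
                    propagate_dna_var = FALSE)

  cfg1 <- sim_config(n_snps = n_snps, pi_functional = 0, pi_asb = pi_asb,
                     fraction_depth_mean = depth, frac_footprint = 0,
                     region_logfc_mean_fp = 0, region_logfc_sd = 0,
                     region_nonspecific = flat, seed = seed + 1)
  d1 <- simulate_design(cfg1)
  set.seed(stage_seed(seed, "gamma_unit"))
  d1$truth[gamma_true != 0, gamma_true := sample(c(-1, 1), .N, replace = TRUE)]
  b1 <- simulate_binding_counts(d1$design, d1$truth, cfg1)
  r1 <- run_asb_pipeline(b1$allele, fdr = fdr)
  m <- merge(r1$asb$overall, d1$truth, by = "snp_id")
  disc <- r1$asb$per_concentration[significant == TRUE, .N, by = concentration]
  disc_vec <- setNames(rep(0L, 3), c("low", "mid", "high"))
  disc_vec[disc$concentration] <- disc$N
  list(
    type1_dast = mean(r0$per_replicate$pvalue < alpha),
    lambda_naive_bound_only = genomic_inflation(naive$pvalue)$lambda_gc,
    sign_agreement = m[gamma_true != 0, mean(sign(z) == sign(gamma_true))],
    discoveries = disc_vec,
    n_snps = n_snps
  )
}

#' Region-level bound/unbound call-gate operating characteristics
#'
#' Across `n_seeds` independent simulations: 20% of regions truly enriched at
#' `log2fc = 2` in the bound fraction (the rest null), depth `depth`,
#' triplicate fractions. Measures the call rate of true regions at the joint
#' gate (log2fc > 1 and FDR < 1%) and the false-call rate of null regions;
#' also runs a fully-null simulation per seed for the pure null-call rate.
#'
#' @param n_seeds independent simulations (default 20).
#' @param n_regions regions per simulation (default 500).
#' @param depth unbound depth per region per replicate (default 200).
#' @param true_lfc log2 enrichment of the true regions (default 2).
#' @param seed base RNG seed.
#' @return list: `power`, `null_call_rate`, `pure_null_call_rate`,
#'   `n_regions_total`.
#' @export
experiment_region_gate <- function(n_seeds = 20, n_regions = 500, depth = 200,
                                   true_lfc = 2, seed = 1) {
  flat <- c(low = 0, mid = 0, high = 0)
  called <- nullcalled <- purenull <- integer(0)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n_snps = n_regions, fraction_depth_mean = depth,
                      frac_footprint = 0.2, region_logfc_mean_fp = true_lfc,
                      region_logfc_mean_bg = 0, region_logfc_sd = 0,
                      region_nonspecific = flat, pi_asb = 0,
                      pi_functional = 0, seed = seed + i * 1000)
    d <- simulate_design(cfg)
    b <- simulate_binding_counts(d$design, d$truth, cfg)
    rt <- region_test(b$region[concentration == "mid"])
    m <- merge(rt, data.table(region_id = d$design$region_id,
                              lfc = d$truth$region_logfc_true),
               by = "region_id")
    called <- c(called, m[lfc == true_lfc, bound_call])
    nullcalled <- c(nullcalled, m[lfc == 0, bound_call])

    cfg0 <- sim_config(n_snps = n_regions, fraction_depth_mean = depth,
                       frac_footprint = 0, region_logfc_mean_fp = 0,
                       region_logfc_mean_bg = 0, region_logfc_sd = 0,
                       region_nonspecific = flat, pi_asb = 0,
                       pi_functional = 0, seed = seed + i * 1000 + 1)
    d0 <- simulate_design(cfg0)
    b0 <- simulate_binding_counts(d0$design, d0$truth, cfg0)
    purenull <- c(purenull,
                  region_test(b0$region[concentration == "mid"])$bound_call)
  }
  list(power = mean(called), null_call_rate = mean(nullcalled),
       pure_null_call_rate = mean(purenull),
       n_regions_total = length(called) + length(nullcalled))
}

#' Independent hypergeometric enumeration of the Fisher exact test
#'
#' Brute-force oracle: for a 2x2 table with margins fixed, enumerates the
#' noncentral support and sums the probabilities of tables no more probable
#' than the observed one (two-sided exact p). Independent of
#' [stats::fisher.test()].
#'
#' @param a,b,c,d cell counts.
#' @return two-sided exact p-value.
#' @export
hypergeom_pvalue <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

#' Conditional-MLE odds ratio by direct likelihood maximization
#'
#' Oracle counterpart of the `fisher.test` estimate: maximizes the
#' noncentral hypergeometric likelihood over log-psi by golden-section
#' search. Returns 0 / Inf on boundary tables.
#'
#' @param a,b,c,d cell counts.
#' @return conditional MLE of the odds ratio.
#' @export
cmle_odds_ratio <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (a == lo && a == hi) return(NaN) # degenerate support
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  x <- lo:hi
  base <- lchoose(m, x) + lchoose(n, k - x)
  negll <- function(lpsi) {
    w <- base + x * lpsi
    -(base[x == a] + a * lpsi - matrixStats_logsumexp(w))
  }
  exp(optimize(negll, c(-30, 30))$minimum)
}

matrixStats_logsumexp <- function(w) {
  mx <- max(w)
  mx + log(sum(exp(w - mx)))
}

#' Fisher test versus enumeration oracle over small tables
#'
#' Enumerates every 2x2 table with grand total up to `max_total`, compares
#' the package's Fisher p-value against [hypergeom_pvalue()], and (on tables
#' with total up to `or_max_total`) the conditional-MLE odds ratio against
#' [cmle_odds_ratio()].
#'
#' @param max_total largest grand total enumerated for the p comparison
#'   (default 40).
#' @param or_max_total largest total for the odds-ratio comparison
#'   (default 16).
#' @return list: `max_abs_diff_p`, `max_rel_diff_or`, `n_tables`,
#'   `n_tables_or`.
#' @export
experiment_fisher_oracle <- function(max_total = 40, or_max_total = 16) {
  tabs <- enumerate_tables(max_total)
  p_impl <- numeric(nrow(tabs))
  p_orac <- numeric(nrow(tabs))
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    p_impl[i] <- fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    p_orac[i] <- hypergeom_pvalue(t[1], t[2], t[3], t[4])
  }
  sub <- tabs[rowSums(tabs) <= or_max_total, , drop = FALSE]
  rel <- numeric(0)
  for (i in seq_len(nrow(sub))) {
    t <- sub[i, ]
    or_impl <- fisher_table(t[1], t[2], t[3], t[4])$odds_ratio
    or_orac <- cmle_odds_ratio(t[1], t[2], t[3], t[4])
    if (is.nan(or_orac)) next # degenerate conditional support
    li <- log(or_impl)
    lo <- log(or_orac)
    if (is.infinite(li) || is.infinite(lo)) {
      rel <- c(rel, if (identical(li, lo)) 0 else Inf)
    } else {
      rel <- c(rel, abs(li - lo))
    }
  }
  list(max_abs_diff_p = max(abs(p_impl - p_orac)),
       max_abs_diff_log_or = if (length(rel)) max(rel) else 0,
       n_tables = nrow(tabs), n_tables_or = nrow(sub))
}

enumerate_tables <- function(max_total) {
  out <- vector("list", max_total)
  for (N in seq_len(max_total)) {
    a <- integer(0); b <- integer(0); cc <- integer(0)
    for (ai in 0:N) for (bi in 0:(N - ai)) {
      ci <- 0:(N - ai - bi)
      a <- c(a, rep.int(ai, length(ci)))
      b <- c(b, rep.int(bi, length(ci)))
      cc <- c(cc, ci)
    }
    out[[N]] <- cbind(a = a, b = b, c = cc, d = N - a - b - cc)
  }
  do.call(rbind, out)
}

#' Enrichment and motif-direction recovery
#'
#' Two parts: (1) a design-scale simulation with the CentiSNP label linked
#' to true functionality at odds ratio `target_or`, recovered with
#' [fisher_enrichment()] of the functional set among CentiSNPs; (2) a
#' direction simulation giving one factor (`CTCF`) orientation-specific
#' effects, analyzed per oligo orientation with [direction_analysis()].
#'
#' @param n_snps design-scale SNPs for the OR recovery (default 20,000).
#' @param n_snps_direction SNPs for the direction analysis (default 4,000).
#' @param target_or CentiSNP odds ratio injected (default 2.5).
#' @param seed RNG seed.
#' @return list: `or_centisnp`, `ci_low`, `ci_high`, `flagged_factors`,
#'   `n_factors_flagged`, `direction_factor_flagged`, `n_snps`.
#' @export
experiment_enrichment_recovery <- function(n_snps = 20000,
                                           n_snps_direction = 4000,
                                           target_or = 2.5, seed = 1) {
  cfg <- sim_config(n_snps = n_snps, pi_functional = 0.2,
                    centisnp_or = target_or, seed = seed)
  d <- simulate_design(cfg)
  er <- fisher_enrichment(d$truth[functional == TRUE, snp_id],
                          d$design[category == "CentiSNP", snp_id],
                          d$design$snp_id, name = "CentiSNP")

  cfgd <- sim_config(n_snps = n_snps_direction, pi_functional = 0.2,
                     direction_factor = "CTCF", rna_depth_mean = 200,
                     dna_depth_mean = 200, seed = seed + 1)
  dd <- simulate_design(cfgd)
  dna <- simulate_dna_counts(dd$design, dd$truth, cfgd)
  rna <- simulate_rna_counts(dd$design, dd$truth, cfgd)
  dp <- estimate_dna_proportion(dna)
  rho <- estimate_overdispersion(aggregate_counts(rna), dp)
  per_oligo <- test_ase(rna, dp, rho)
  meta <- call_significant(fixed_effects(per_oligo,
                                         by = c("snp_id", "orientation")))
  da <- direction_analysis(meta, dd$design)
  flagged <- da[flagged == TRUE, annotation]
  list(or_centisnp = er$odds_ratio, ci_low = er$ci95_low,
       ci_high = er$ci95_high,
       flagged_factors = flagged,
       n_factors_flagged = length(flagged),
       direction_factor_flagged = "CTCF" %in% flagged,
       n_snps = n_snps)
}

annotation <- NULL
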