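#' Simulation configuration for the synthetic reporter-assay generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_design()], [simulate_dna_counts()], [simulate_rna_counts()],
#' [simulate_rna_molecules()] and [simulate_binding_counts()]. Defaults mirror
#' the assay's replicate structure: nine biological RNA replicates, seven
#' plasmid DNA library replicates, and bound/unbound binding fractions in
#' triplicate at three protein concentrations.
#'
#' @param n_snps number of biallelic SNPs (each carried by two oligo
#'   orientations on a 200 bp regulatory insert, SNP centered).
#' @param pi_functional fraction of SNPs with a true allele-specific
#'   expression effect.
#' @param tau_beta SD of true ASE effects on the log-odds scale.
#' @param pi_asb fraction of SNPs with a true allele-specific binding effect.
#' @param tau_gamma SD of true binding effects (log-odds).
#' @param effect_corr latent Gaussian correlation coupling ASE and ASB:
#'   applied both to the functional/bound indicators and to the effect-size
#'   draws. The default 0.5 encodes the biology the binding assay probes —
#'   binding disruption is one mechanism behind expression effects — so SNPs
#'   with ASE are enriched for ASB in the default dataset; 0 decouples the
#'   assays.
#' @param rho_true beta-binomial overdispersion of allelic proportions in
#'   `[0, 0.5)`; the per-draw variance inflation is `1 + (N - 1) * rho`.
#' @param dna_depth_mean,rna_depth_mean,fraction_depth_mean expected molecules
#'   per SNP per replicate (summed over the two oligo orientations) for the
#'   plasmid DNA library, the reporter RNA, and each binding fraction.
#' @param nb_size negative-binomial size parameter governing depth variation
#'   across SNPs; `Inf` gives Poisson totals.
#' @param lib_imbalance_conc concentration of the symmetric Beta prior on the
#'   plasmid-library reference-allele proportion (larger = closer to 0.5).
#' @param mu_dup mean number of extra PCR copies per molecule (copies are
#'   `1 + Poisson(mu_dup)`, duplicates share the molecule's UMI).
#' @param umi_length UMI length in bases.
#' @param n_rna_reps,n_dna_reps,n_bind_reps replicate counts.
#' @param n_concentrations number of protein concentrations for the binding
#'   assay.
#' @param conc_scale per-concentration multiplier on the binding effect
#'   (effective allelic affinity shift is `gamma_true * conc_scale`). The
#'   default is monotone in concentration, reflecting incomplete binding at
#'   the low concentration.
#' @param region_nonspecific per-concentration nonspecific-binding background:
#'   the bound-fraction depth for a region is
#'   `fraction_depth_mean * ((1 - ns) * 2^logfc + ns)`. Highest at the high
#'   concentration, where nonspecific capture is expected.
#' @param frac_footprint fraction of regions carrying the target-factor
#'   footprint annotation.
#' @param region_logfc_mean_fp,region_logfc_mean_bg,region_logfc_sd mean log2
#'   bound/unbound occupancy for footprint and background regions, and its SD.
#' @param frac_negctrl target fraction of SNPs labelled negative controls
#'   (guaranteed effect-free).
#' @param p_centisnp baseline probability that a non-functional SNP carries
#'   the CentiSNP label.
#' @param centisnp_or odds ratio linking the CentiSNP label to true
#'   functionality (makes enrichment recovery testable).
#' @param frac_motif fraction of SNPs annotated with a transcription-factor
#'   motif (factor and strand drawn uniformly).
#' @param motif_factors character vector of factor names to draw motifs from.
#' @param direction_factor optional factor name given orientation-specific
#'   effects: its SNPs have an ASE effect only on the oligo whose reporter
#'   transcription direction is *opposite* to the motif strand. `NULL`
#'   disables orientation-specific effects.
#' @param direction_beta absolute log-odds effect (random sign) used for
#'   `direction_factor` SNPs.
#' @param seed master RNG seed.
#'
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 100, seed = 1)
#' cfg$n_rna_reps
sim_config <- function(n_snps = 1000,
                       pi_functional = 0.2,
                       tau_beta = 0.5,
                       pi_asb = 0.2,
                       tau_gamma = 0.5,
                       effect_corr = 0.5,
                       rho_true = 0.02,
                       dna_depth_mean = 100,
                       rna_depth_mean = 100,
                       fraction_depth_mean = 100,
                       nb_size = 10,
                       lib_imbalance_conc = 50,
                       mu_dup = 1,
                       umi_length = 10,
                       n_rna_reps = 9,
                       n_dna_reps = 7,
                       n_bind_reps = 3,
                       n_concentrations = 3,
                       conc_scale = c(low = 0.7, mid = 1.0, high = 1.1),
                       region_nonspecific = c(low = 0.10, mid = 0.05, high = 0.30),
                       frac_footprint = 0.2,
                       region_logfc_mean_fp = 2,
                       region_logfc_mean_bg = 0,
                       region_logfc_sd = 0.5,
                       frac_negctrl = 0.1,
                       p_centisnp = 0.25,
                       centisnp_or = 2.5,
                       frac_motif = 0.5,
                       motif_factors = c("NFKB1", "CTCF", "CREB1", "AML1",
                                         "STAT1", "IRF4", "POU2F1", "SPI1"),
                       direction_factor = NULL,
                       direction_beta = 0.75,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_num <- function(field, lo = -Inf, hi = Inf, len = 1L,
                      strict_lo = FALSE, strict_hi = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != len || anyNA(x)) {
      stop_config(field, sprintf("must be numeric of length %d", len))
    }
    bad <- if (strict_lo) any(x <= lo) else any(x < lo)
    bad <- bad || if (strict_hi) any(x >= hi) else any(x > hi)
    if (bad) {
      stop_config(field, sprintf("must lie in %s%s, %s%s",
                                 if (strict_lo) "(" else "[", lo, hi,
                                 if (strict_hi) ")" else "]"))
    }
    invisible(x)
  }
  chk_num("n_snps", 1, Inf)
  if (cfg$n_snps != round(cfg$n_snps)) stop_config("n_snps", "must be an integer")
  for (f in c("pi_functional", "pi_asb", "frac_footprint", "frac_negctrl",
              "p_centisnp", "frac_motif")) {
    chk_num(f, 0, 1)
  }
  chk_num("effect_corr", -1, 1)
  chk_num("rho_true", 0, 0.5, strict_hi = TRUE)
  for (f in c("dna_depth_mean", "rna_depth_mean", "fraction_depth_mean")) {
    chk_num(f, 0, Inf, strict_lo = TRUE)
  }
  chk_num("nb_size", 0, Inf, strict_lo = TRUE)
  chk_num("lib_imbalance_conc", 0, Inf, strict_lo = TRUE)
  chk_num("mu_dup", 0, Inf)
  chk_num("umi_length", 1, 31)
  for (f in c("n_rna_reps", "n_dna_reps", "n_bind_reps", "n_concentrations")) {
    chk_num(f, 1, Inf)
    if (cfg[[f]] != round(cfg[[f]])) stop_config(f, "must be an integer")
  }
  chk_num("tau_beta", 0, Inf)
  chk_num("tau_gamma", 0, Inf)
  chk_num("centisnp_or", 0, Inf, strict_lo = TRUE)
  chk_num("direction_beta", 0, Inf)
  chk_num("region_logfc_sd", 0, Inf)
  chk_num("conc_scale", 0, Inf, len = cfg$n_concentrations)
  chk_num("region_nonspecific", 0, 1, len = cfg$n_concentrations)
  chk_num("seed", 0, 2^31 - 1)
  if (!is.null(cfg$direction_factor) &&
      !cfg$direction_factor %in% cfg$motif_factors) {
    stop_config("direction_factor", "must be one of motif_factors")
  }
  invisible(cfg)
}

# Concentration labels: low/mid/high for the canonical 3, else c1, c2, ...
conc_labels <- function(cfg) {
  nm <- names(cfg$conc_scale)
  if (!is.null(nm) && all(nzchar(nm))) return(nm)
  if (cfg$n_concentrations == 3) c("low", "mid", "high")
  else paste0("c", seq_len(cfg$n_concentrations))
}
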