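#' Simulate the biallelic oligo library design and its ground truth
#'
#' Generates one design row per SNP (two oligo orientations per SNP, 200 bp
#' regulatory insert with the SNP centered — the insert constants are recorded
#' as attributes) together with a ground-truth table holding the latent
#' parameters the downstream tests try to recover.
#'
#' Category assignment guarantees negative controls carry no effect
#' (`beta_true = gamma_true = 0`), and links the CentiSNP label to true
#' functionality at odds ratio `centisnp_or` so enrichment recovery is
#' testable. If `direction_factor` is set, SNPs bearing that motif get an ASE
#' effect only on the oligo transcribed opposite to the motif strand.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `design` and `truth` (both `data.table`):
#'   * `design`: `snp_id`, `region_id`, `ref_allele`, `alt_allele`,
#'     `oligo_orientations` (`"fwd,rev"`), `motif_factor`, `motif_strand`,
#'     `category`, `has_target_footprint`.
#'   * `truth`: `snp_id`, `functional`, `beta_true`, `beta_fwd`, `beta_rev`,
#'     `gamma_true`, `p_dna_true`, `region_logfc_true`.
#' @export
#' @examples
#' d <- simulate_design(sim_config(n_snps = 50, seed = 3))
#' table(d$design$category)
simulate_design <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- as.integer(cfg$n_snps)
  set.seed(stage_seed(cfg$seed, "design"))

  snp_id <- sprintf("snp%06d", seq_len(n))
  region_id <- sprintf("reg%06d", seq_len(n))

  bases <- c("A", "C", "G", "T")
  ref_allele <- sample(bases, n, replace = TRUE)
  alt_allele <- vapply(ref_allele,
                       function(r) sample(setdiff(bases, r), 1L), character(1))

  # Latent functionality for ASE and ASB, coupled through a Gaussian copula.
  u1 <- rnorm(n)
  u2 <- cfg$effect_corr * u1 + sqrt(1 - cfg$effect_corr^2) * rnorm(n)
  functional <- u1 < qnorm(cfg$pi_functional)
  asb_active <- u2 < qnorm(cfg$pi_asb)

  e1 <- rnorm(n)
  e2 <- cfg$effect_corr * e1 + sqrt(1 - cfg$effect_corr^2) * rnorm(n)
  beta_true <- ifelse(functional, cfg$tau_beta * e1, 0)
  gamma_true <- ifelse(asb_active, cfg$tau_gamma * e2, 0)

  # CentiSNP label at the configured odds ratio with functionality.
  odds_base <- cfg$p_centisnp / (1 - cfg$p_centisnp)
  p_centi_f <- (odds_base * cfg$centisnp_or) / (1 + odds_base * cfg$centisnp_or)
  centi <- runif(n) < ifelse(functional, p_centi_f, cfg$p_centisnp)

  # Negative controls are drawn among non-CentiSNP, non-functional SNPs so the
  # CentiSNP x functional contingency is untouched; they are forced null.
  avail <- !centi & !functional & gamma_true == 0
  p_avail <- max(mean(avail), 1e-12)
  negctrl <- avail & runif(n) < min(1, cfg$frac_negctrl / p_avail)
  category <- ifelse(centi, "CentiSNP",
                     ifelse(negctrl, "negative_control",
                            sample(c("eQTL", "GWAS"), n, replace = TRUE)))
  beta_true[negctrl] <- 0
  gamma_true[negctrl] <- 0
  functional <- beta_true != 0

  # Motif annotations.
  has_motif <- runif(n) < cfg$frac_motif
  motif_factor <- rep(NA_character_, n)
  motif_factor[has_motif] <- sample(cfg$motif_factors, sum(has_motif),
                                    replace = TRUE)
  motif_strand <- rep(NA_character_, n)
  motif_strand[has_motif] <- sample(c("+", "-"), sum(has_motif), replace = TRUE)

  # Orientation-specific effects: shared beta on both oligos by default; the
  # direction factor's SNPs are effective only in the "opposite"
  # configuration (reporter transcription opposite to the motif strand).
  beta_fwd <- beta_true
  beta_rev <- beta_true
  if (!is.null(cfg$direction_factor)) {
    idx <- which(!is.na(motif_factor) & motif_factor == cfg$direction_factor &
                   category != "negative_control")
    sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
    eff <- cfg$direction_beta * sgn
    # strand "+": fwd oligo matches the motif strand, rev is opposite.
    plus <- motif_strand[idx] == "+"
    beta_fwd[idx] <- ifelse(plus, 0, eff)
    beta_rev[idx] <- ifelse(plus, eff, 0)
    beta_true[idx] <- eff
    functional[idx] <- TRUE
  }

  # Plasmid-library reference proportion and region occupancy truth.
  p_dna_true <- rbeta(n, cfg$lib_imbalance_conc, cfg$lib_imbalance_conc)
  p_dna_true <- clamp(p_dna_true, 1e-6, 1 - 1e-6)
  has_target_footprint <- runif(n) < cfg$frac_footprint
  region_logfc_true <- rnorm(
    n,
    mean = ifelse(has_target_footprint, cfg$region_logfc_mean_fp,
                  cfg$region_logfc_mean_bg),
    sd = cfg$region_logfc_sd
  )

  design <- data.table(
    snp_id = snp_id, region_id = region_id,
    ref_allele = ref_allele, alt_allele = alt_allele,
    oligo_orientations = "fwd,rev",
    motif_factor = motif_factor, motif_strand = motif_strand,
    category = category, has_target_footprint = has_target_footprint
  )
  truth <- data.table(
    snp_id = snp_id, functional = functional,
    beta_true = beta_true, beta_fwd = beta_fwd, beta_rev = beta_rev,
    gamma_true = gamma_true, p_dna_true = p_dna_true,
    region_logfc_true = region_logfc_true
  )
  attr(design, "insert_bp") <- 200L
  attr(design, "oligo_bp") <- 230L
  list(design = design, truth = truth)
}
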