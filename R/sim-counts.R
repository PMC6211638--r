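# Count-level simulators: plasmid DNA, reporter RNA, and binding fractions.

# Total molecule counts per record: NB(mean, size), Poisson in the size -> Inf
# limit.
draw_depth <- function(n, mean, size) {
  if (is.infinite(size)) as.integer(rpois(n, lambda = mean))
  else as.integer(rnbinom(n, size = size, mu = mean))
}

# Beta-mixed binomial: p drawn around mu with Var = mu (1 - mu) rho, then
# Binomial(N, p); variance inflation 1 + (N - 1) rho.
draw_allelic <- function(n_total, mu, rho) {
  mu <- clamp(mu, 1e-9, 1 - 1e-9)
  if (rho <= 0) {
    p <- mu
  } else {
    p <- rbeta(length(n_total), mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
    p <- clamp(p, 0, 1)
  }
  as.integer(rbinom(length(n_total), size = n_total, prob = p))
}

# Map a shared uniform through the Beta quantile with mean mu and
# correlation-parameter rho (comonotone across orientations of a SNP, so the
# replicate-level perturbation is shared and orientation-pooled counts stay
# beta-binomial at rho).
beta_quantile_mix <- function(u, mu, rho) {
  mu <- clamp(mu, 1e-9, 1 - 1e-9)
  if (rho <= 0) return(mu)
  clamp(qbeta(u, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho), 0, 1)
}

#' Simulate plasmid DNA library allele counts
#'
#' Per SNP, orientation and DNA replicate, the total molecule count is
#' negative-binomial around half of `dna_depth_mean` (two orientations per
#' SNP) and the reference count is binomial at the SNP's true library
#' proportion: the plasmid library carries imbalance but no overdispersion
#' beyond sampling.
#'
#' @param design,truth output of [simulate_design()].
#' @param config the [sim_config()] used to generate them.
#' @return `data.table` with `snp_id`, `orientation`, `replicate`,
#'   `fraction = "DNA"`, `ref_count`, `alt_count`.
#' @export
simulate_dna_counts <- function(design, truth, config) {
  validate_sim_config(config)
  check_truth_covers(design, truth)
  out <- vector("list", config$n_dna_reps)
  base <- data.table(snp_id = truth$snp_id, p = truth$p_dna_true)
  per_orient <- rbind(copy(base)[, orientation := "fwd"],
                      copy(base)[, orientation := "rev"])
  for (r in seq_len(config$n_dna_reps)) {
    set.seed(stage_seed(config$seed, "dna", r))
    n <- nrow(per_orient)
    tot <- draw_depth(n, config$dna_depth_mean / 2, config$nb_size)
    ref <- rbinom(n, size = tot, prob = per_orient$p)
    out[[r]] <- data.table(
      snp_id = per_orient$snp_id, orientation = per_orient$orientation,
      replicate = r, fraction = "DNA",
      ref_count = ref, alt_count = tot - ref
    )
  }
  rbindlist(out)
}

# RNA molecule counts for one replicate (internal; shared by the count-level
# and molecule-level generators so the two agree draw-for-draw). One Beta
# perturbation per SNP per replicate, shared across orientations.
draw_rna_rep <- function(truth, config, rep_index) {
  set.seed(stage_seed(config$seed, "rna", rep_index))
  n <- nrow(truth)
  tot_f <- draw_depth(n, config$rna_depth_mean / 2, config$nb_size)
  tot_r <- draw_depth(n, config$rna_depth_mean / 2, config$nb_size)
  u <- runif(n)
  mu_f <- plogis(qlogis(truth$p_dna_true) + truth$beta_fwd)
  mu_r <- plogis(qlogis(truth$p_dna_true) + truth$beta_rev)
  p_f <- beta_quantile_mix(u, mu_f, config$rho_true)
  p_r <- beta_quantile_mix(u, mu_r, config$rho_true)
  ref_f <- as.integer(rbinom(n, tot_f, p_f))
  ref_r <- as.integer(rbinom(n, tot_r, p_r))
  data.table(
    snp_id = rep(truth$snp_id, 2L),
    orientation = rep(c("fwd", "rev"), each = n),
    replicate = rep_index, fraction = "RNA",
    ref_count = c(ref_f, ref_r),
    alt_count = c(tot_f - ref_f, tot_r - ref_r)
  )
}

#' Simulate deduplicated reporter RNA allele counts
#'
#' Per SNP, orientation and RNA replicate, draws the total molecule count,
#' shifts the reference-allele proportion off the library proportion by the
#' oligo's true log-odds effect, injects beta-binomial overdispersion
#' (`rho_true`), and emits molecule-level ref/alt counts. This is the
#' molecule-level ground truth that UMI deduplication of
#' [simulate_rna_molecules()] output recovers.
#'
#' @inheritParams simulate_dna_counts
#' @param replicates integer vector of replicate indices (default all).
#' @return `data.table` with `snp_id`, `orientation`, `replicate`,
#'   `fraction = "RNA"`, `ref_count`, `alt_count`.
#' @export
simulate_rna_counts <- function(design, truth, config, replicates = NULL) {
  validate_sim_config(config)
  check_truth_covers(design, truth)
  reps <- replicates %||% seq_len(config$n_rna_reps)
  tr <- as_dt(truth)
  rbindlist(lapply(reps, function(r) draw_rna_rep(tr, config, r)))
}

#' Simulate UMI-tagged read-level RNA molecule records
#'
#' Takes the molecule counts of [simulate_rna_counts()] (same RNG stream, so
#' the two agree exactly), assigns each molecule a UMI uniform over
#' `4^umi_length` (collisions allowed), and emits each molecule
#' `1 + Poisson(mu_dup)` times; PCR duplicates share the molecule's UMI.
#'
#' UMIs are returned as integer codes in `[0, 4^umi_length)` for compactness;
#' [umi_int_to_string()] / [write_molecules()] convert to ACGT strings.
#'
#' @inheritParams simulate_rna_counts
#' @return `data.table` of reads: `snp_id`, `orientation`, `allele`
#'   (`"ref"`/`"alt"`), `umi` (integer code), `replicate`, `fraction = "RNA"`,
#'   with attribute `umi_length`.
#' @export
simulate_rna_molecules <- function(design, truth, config, replicates = NULL) {
  validate_sim_config(config)
  check_truth_covers(design, truth)
  reps <- replicates %||% seq_len(config$n_rna_reps)
  tr <- as_dt(truth)
  umi_space <- 4^config$umi_length
  out <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    r <- reps[i]
    cnt <- draw_rna_rep(tr, config, r)
    long <- melt(cnt, measure.vars = c("ref_count", "alt_count"),
                 variable.name = "allele", value.name = "n_mol")
    long[, allele := ifelse(allele == "ref_count", "ref", "alt")]
    long <- long[n_mol > 0L]
    # one row per molecule
    mol <- long[rep(seq_len(.N), n_mol),
                .(snp_id, orientation, allele, replicate, fraction)]
    set.seed(stage_seed(config$seed, "rna_umi", r))
    mol[, umi := floor(runif(.N) * umi_space)]
    copies <- 1L + rpois(nrow(mol), config$mu_dup)
    reads <- mol[rep(seq_len(.N), copies)]
    out[[i]] <- reads
  }
  res <- rbindlist(out)
  setcolorder(res, c("snp_id", "orientation", "allele", "umi", "replicate",
                     "fraction"))
  setattr(res, "umi_length", as.integer(config$umi_length))
  res[]
}

#' Simulate bound/unbound binding-fraction counts
#'
#' For each SNP, concentration and replicate: the unbound fraction samples
#' alleles at the library proportion; the bound fraction shifts the log-odds
#' by `gamma_true * conc_scale[concentration]`. Bound totals scale with the
#' region's true occupancy `2^region_logfc_true`, blended with the
#' per-concentration nonspecific background. Both fractions carry the
#' generator's beta-binomial overdispersion. Region-level totals (both
#' alleles pooled) are returned alongside, coupled to the same draws.
#'
#' @inheritParams simulate_dna_counts
#' @return list with `allele` (`snp_id`, `concentration`, `replicate`,
#'   `fraction` in `bound`/`unbound`, `ref_count`, `alt_count`) and `region`
#'   (`region_id`, `concentration`, `replicate`, `fraction`, `count`).
#' @export
simulate_binding_counts <- function(design, truth, config) {
  validate_sim_config(config)
  check_truth_covers(design, truth)
  labels <- conc_labels(config)
  tr <- as_dt(truth)[as_dt(design)[, .(snp_id, region_id)], on = "snp_id"]
  n <- nrow(tr)
  allele_out <- list()
  region_out <- list()
  idx <- 0L
  for (ci in seq_len(config$n_concentrations)) {
    scale_c <- config$conc_scale[ci]
    ns_c <- config$region_nonspecific[ci]
    mu_bound_depth <- config$fraction_depth_mean *
      ((1 - ns_c) * 2^tr$region_logfc_true + ns_c)
    p_bound <- plogis(qlogis(tr$p_dna_true) + tr$gamma_true * scale_c)
    for (r in seq_len(config$n_bind_reps)) {
      set.seed(stage_seed(config$seed, paste0("bind", ci), r))
      tot_u <- draw_depth(n, config$fraction_depth_mean, config$nb_size)
      ref_u <- draw_allelic(tot_u, tr$p_dna_true, config$rho_true)
      tot_b <- draw_depth(n, mu_bound_depth, config$nb_size)
      ref_b <- draw_allelic(tot_b, p_bound, config$rho_true)
      idx <- idx + 1L
      allele_out[[idx]] <- data.table(
        snp_id = rep(tr$snp_id, 2L),
        concentration = labels[ci], replicate = r,
        fraction = rep(c("unbound", "bound"), each = n),
        ref_count = c(ref_u, ref_b),
        alt_count = c(tot_u - ref_u, tot_b - ref_b)
      )
      region_out[[idx]] <- data.table(
        region_id = rep(tr$region_id, 2L),
        concentration = labels[ci], replicate = r,
        fraction = rep(c("unbound", "bound"), each = n),
        count = c(tot_u, tot_b)
      )
    }
  }
  list(allele = rbindlist(allele_out), region = rbindlist(region_out))
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_design()], [simulate_dna_counts()],
#' [simulate_rna_counts()] and [simulate_binding_counts()] under one config.
#'
#' @param config a [sim_config()].
#' @param binding include the binding-assay fractions? (default `TRUE`)
#' @return list with `design`, `truth`, `dna`, `rna`, and (optionally)
#'   `binding` (list of `allele` and `region` tables), plus the `config`.
#' @export
simulate_dataset <- function(config, binding = TRUE) {
  d <- simulate_design(config)
  out <- list(
    design = d$design, truth = d$truth,
    dna = simulate_dna_counts(d$design, d$truth, config),
    rna = simulate_rna_counts(d$design, d$truth, config),
    config = config
  )
  if (binding) out$binding <- simulate_binding_counts(d$design, d$truth, config)
  out
}

check_truth_covers <- function(design, truth) {
  if (!all(design$snp_id %in% truth$snp_id)) {
    stop("truth table does not cover every SNP in the design", call. = FALSE)
  }
  invisible(TRUE)
}
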