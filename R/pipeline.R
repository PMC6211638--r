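# End-to-end orchestration: molecule table (or counts) -> ASE calls with
# inflation diagnostics; binding fractions -> delta-AST ASB calls and
# region-level bound/unbound calls.

#' Run the allele-specific expression pipeline
#'
#' dedup (optional) -> per-SNP counts (orientations pooled) -> testability
#' filter -> DNA proportions -> genome-wide overdispersion -> per-replicate
#' beta-binomial ASE tests -> fixed-effects meta-analysis -> BH correction
#' and FDR calls -> genomic-inflation diagnostic.
#'
#' `rna` may be a molecule table (with a `umi` column; deduplicated unless
#' `dedup = FALSE`, in which case every read counts) or a ready allele-count
#' table. When `rho` is `NULL` it is estimated from the deduplicated counts
#' with the between-replicate estimator; the duplicate-retention ablation
#' (`dedup = FALSE`) keeps using a molecule-level `rho`, so the two arms
#' differ only in the counts tested — see the methods vignette.
#'
#' @param rna RNA molecule table or allele-count table.
#' @param dna DNA allele-count table.
#' @param min_rna_total,min_dna_total testability filter thresholds.
#' @param rho overdispersion passed to [test_ase()]; `NULL` to estimate.
#' @param fdr FDR threshold for ASE calls (default 0.10).
#' @param dedup collapse PCR duplicates by UMI (molecule input only).
#' @param propagate_dna_var forward DNA-proportion variance into the
#'   per-replicate SEs (shared component handled by [fixed_effects()]).
#' @return list: `counts`, `dna_prop`, `rho` (`dispersion_estimate`),
#'   `per_replicate`, `meta` (with `qvalue`/`significant`), `inflation`,
#'   `filter_summary`, `manifest`.
#' @export
run_ase_pipeline <- function(rna, dna, min_rna_total = 5, min_dna_total = 10,
                             rho = NULL, fdr = 0.10, dedup = TRUE,
                             propagate_dna_var = TRUE) {
  counts <- if ("umi" %in% names(rna)) {
    if (dedup) dedup_umi(rna) else count_reads(rna)
  } else {
    as_dt(rna)
  }
  counts <- aggregate_counts(counts, pool_orientation = TRUE)
  flt <- filter_testable(counts, dna, min_rna_total, min_dna_total)
  dna_prop <- estimate_dna_proportion(flt$dna)
  if (is.null(rho)) {
    rho <- estimate_overdispersion(flt$rna, dna_prop, method = "replicates")
  }
  per_rep <- test_ase(flt$rna, dna_prop, rho,
                      propagate_dna_var = propagate_dna_var)
  meta <- fixed_effects(per_rep, by = "snp_id")
  meta <- call_significant(meta, fdr = fdr)
  infl <- genomic_inflation(meta$pvalue)
  manifest <- list(
    package = as.character(utils::packageVersion("mprastats")),
    stage = "ase",
    params = list(min_rna_total = min_rna_total, min_dna_total = min_dna_total,
                  fdr = fdr, dedup = dedup,
                  rho = if (inherits(rho, "dispersion_estimate")) rho$rho else rho,
                  propagate_dna_var = propagate_dna_var),
    n_snps_tested = nrow(meta),
    n_significant = attr(meta, "n_significant")
  )
  list(counts = flt$rna, dna_prop = dna_prop, rho = rho,
       per_replicate = per_rep, meta = meta, inflation = infl,
       filter_summary = flt$summary, manifest = manifest)
}

#' Run the allele-specific binding pipeline
#'
#' Reference proportion from the pooled bound+unbound counts, per-fraction /
#' per-concentration overdispersion (between-replicate estimator),
#' per-replicate allelic tests in each fraction (no DNA-variance
#' propagation: the shared reference cancels in the contrast), delta-AST per
#' replicate and concentration, Stouffer combination within and across
#' concentrations with BH/FDR calls, and (when region counts are given) the
#' region-level NB bound/unbound test per concentration.
#'
#' @param binding allele-count table with `fraction` in `bound`/`unbound`,
#'   `concentration`, `replicate`.
#' @param region_counts optional long region-count table (see
#'   [region_test()]).
#' @param fdr FDR for ASB calls (default 0.10).
#' @param lfc_threshold,region_fdr the joint region-call gate (defaults 1 and
#'   0.01).
#' @return list: `dna_prop` (pooled reference proportions), `rho_table`,
#'   `per_replicate` (delta-AST rows), `asb` (list from [combine_asb()]),
#'   `regions` (per-concentration [region_test()] results or `NULL`),
#'   `manifest`.
#' @export
run_asb_pipeline <- function(binding, region_counts = NULL, fdr = 0.10,
                             lfc_threshold = 1, region_fdr = 0.01) {
  x <- as_dt(binding)
  require_cols(x, c("snp_id", "fraction", "concentration", "replicate",
                    "ref_count", "alt_count"), "binding count table")
  # reference proportion: combined unbound and bound DNA
  dna_prop <- estimate_dna_proportion(x)

  rho_table <- x[, {
    est <- estimate_overdispersion(.SD, method = "replicates")
    .(rho = est$rho)
  }, by = .(fraction, concentration)]

  ase <- test_ase(x, dna_prop, rho = rho_table, propagate_dna_var = FALSE)
  d <- dast(ase[fraction == "bound"], ase[fraction == "unbound"])
  asb <- combine_asb(d, fdr = fdr)

  regions <- NULL
  if (!is.null(region_counts)) {
    rc <- as_dt(region_counts)
    regions <- lapply(split(rc, rc$concentration), function(sub) {
      region_test(sub, lfc_threshold = lfc_threshold, fdr = region_fdr)
    })
  }
  manifest <- list(
    package = as.character(utils::packageVersion("mprastats")),
    stage = "asb",
    params = list(fdr = fdr, lfc_threshold = lfc_threshold,
                  region_fdr = region_fdr),
    n_snps_tested = nrow(asb$overall),
    n_asb_overall = sum(asb$overall$significant),
    n_asb_union = length(asb$union_calls)
  )
  list(dna_prop = dna_prop, rho_table = rho_table, per_replicate = d,
       asb = asb, regions = regions, manifest = manifest)
}
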