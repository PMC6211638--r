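# Differential allele-specific test (delta-AST): contrast allelic imbalance
# in the bound fraction against the unbound fraction.

#' Differential allele-specific test between bound and unbound fractions
#'
#' Pairs per-replicate allelic-imbalance results for the two fractions (both
#' computed by [test_ase()] against the same pooled bound+unbound reference
#' proportion) and tests their difference:
#' `delta_beta = beta_bound - beta_unbound`,
#' `se_delta = sqrt(se_b^2 + se_u^2)`, `z = delta_beta/se_delta`, two-sided
#' normal p. Because both betas subtract the same `logit(p0)`, any plasmid
#' library imbalance — and the error in estimating it — cancels in the
#' difference; compute the inputs with `propagate_dna_var = FALSE` so the
#' cancelled component is not double-counted in `se_delta`.
#'
#' @param bound,unbound [test_ase()] results for the two fractions, sharing
#'   `snp_id`, `replicate` (and `concentration` if present).
#' @return `data.table` with the pairing columns plus `delta_beta`,
#'   `se_delta`, `z`, `pvalue`. SNP/replicate combinations present in only
#'   one fraction are dropped and listed in the `"untestable"` attribute.
#' @export
dast <- function(bound, unbound) {
  b <- as_dt(bound)
  u <- as_dt(unbound)
  for (x in list(b, u)) require_cols(x, c("snp_id", "beta", "se"),
                                     "ASE result table")
  keys <- setdiff(intersect(id_cols_of(b), id_cols_of(u)), "fraction")
  if (length(keys) == 0L) stop("no columns to pair bound/unbound on",
                               call. = FALSE)
  m <- merge(b[, c(keys, "beta", "se"), with = FALSE],
             u[, c(keys, "beta", "se"), with = FALSE],
             by = keys, suffixes = c("_b", "_u"))
  dropped <- union(
    b[!m, on = keys, unique(snp_id)],
    u[!m, on = keys, unique(snp_id)]
  )
  res <- m[, {
    d <- beta_b - beta_u
    s <- sqrt(se_b^2 + se_u^2)
    .(delta_beta = d, se_delta = s, z = d / s, pvalue = z_pvalue(d / s))
  }, by = keys]
  setattr(res, "untestable", dropped)
  res[]
}

#' Combine delta-AST results into per-concentration and overall ASB calls
#'
#' Stouffer's method over replicates within each protein concentration, then
#' Stouffer's method again over the per-concentration combined z-scores for
#' the overall call. BH correction is applied within each level; calls are
#' made at `fdr`. The union of per-concentration call sets is reported
#' alongside the combined-Z overall calls.
#'
#' @param dast_results output of [dast()] with `snp_id`, `concentration`,
#'   `replicate`, `z`.
#' @param fdr FDR threshold for calls (default 0.10).
#' @return list with
#'   * `per_concentration`: `snp_id`, `concentration`, `z`, `pvalue`,
#'     `qvalue`, `significant`, `k`;
#'   * `overall`: `snp_id`, `z`, `pvalue`, `qvalue`, `significant`, `k`;
#'   * `union_calls`: SNP ids significant in at least one concentration.
#' @export
combine_asb <- function(dast_results, fdr = 0.10) {
  x <- as_dt(dast_results)
  require_cols(x, c("snp_id", "concentration", "z"), "delta-AST table")
  per <- x[, {
    s <- stouffer(z)
    .(z = s$z, pvalue = s$pvalue, k = .N)
  }, by = .(snp_id, concentration)]
  per[, qvalue := adjust_pvalues(pvalue), by = concentration]
  per[, significant := qvalue < fdr]
  overall <- per[, {
    s <- stouffer(z)
    .(z = s$z, pvalue = s$pvalue, k = .N)
  }, by = snp_id]
  overall[, qvalue := adjust_pvalues(pvalue)]
  overall[, significant := qvalue < fdr]
  list(per_concentration = per[],
       overall = overall[],
       union_calls = per[significant == TRUE, unique(snp_id)])
}

beta_b <- beta_u <- se_b <- se_u <- NULL
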