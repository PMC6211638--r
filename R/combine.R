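# Combining per-replicate results: fixed-effects and Stouffer meta-analysis,
# multiple-testing correction, genomic inflation.

#' Fixed-effects (inverse-variance) meta-analysis of per-replicate results
#'
#' Standard inverse-variance weighting: `w_i = 1/se_i^2`,
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`. If the input
#' carries a `var_dna` column (the DNA-proportion variance component from
#' [test_ase()], identical across replicates of a SNP because every replicate
#' is contrasted against the same plasmid proportion), that shared component
#' is removed from the weights and added back once:
#' `w_i = 1/(se_i^2 - var_dna)`, `var_meta = 1/sum(w) + var_dna`. With
#' `var_dna = 0` this is exactly the textbook estimator.
#'
#' @param results `data.table` with `beta`, `se`, optional `var_dna`, and the
#'   grouping columns in `by`.
#' @param by grouping column(s), default `"snp_id"`.
#' @return `data.table` with `by` columns plus `beta_meta`, `se_meta`,
#'   `z_meta`, `pvalue`, `k` (replicates combined).
#' @export
#' @examples
#' r <- data.frame(snp_id = "s", beta = c(1, 1), se = c(1, 1))
#' fixed_effects(r) # beta_meta 1, se_meta 1/sqrt(2)
fixed_effects <- function(results, by = "snp_id") {
  x <- as_dt(results)
  require_cols(x, c(by, "beta", "se"), "result table")
  if (nrow(x) == 0L) stop("no results to combine", call. = FALSE)
  if (any(x$se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  if (!"var_dna" %in% names(x)) x[, var_dna := 0]
  x[, {
    w <- 1 / pmax(se^2 - var_dna, 1e-12)
    vd <- var_dna[1]
    bm <- sum(w * beta) / sum(w)
    vm <- 1 / sum(w) + vd
    sm <- sqrt(vm)
    .(beta_meta = bm, se_meta = sm, z_meta = bm / sm,
      pvalue = z_pvalue(bm / sm), k = .N)
  }, by = by]
}

#' Stouffer's method for combining z-scores
#'
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`; unweighted by default (all
#' `w_i = 1`, giving `Z = sum(z)/sqrt(k)`).
#'
#' @param z numeric vector of z-scores.
#' @param weights optional weights.
#' @return list with `z` (combined) and `pvalue` (two-sided).
#' @export
#' @examples
#' stouffer(c(1, 1))$z # sqrt(2)
stouffer <- function(z, weights = NULL) {
  if (length(z) == 0L) stop("no z-scores to combine", call. = FALSE)
  if (anyNA(z)) stop("z-scores contain NA", call. = FALSE)
  w <- weights %||% rep(1, length(z))
  stopifnot(length(w) == length(z), all(w > 0))
  Z <- sum(w * z) / sqrt(sum(w^2))
  list(z = Z, pvalue = z_pvalue(Z))
}

#' Multiple-testing correction
#'
#' Benjamini–Hochberg step-up (with monotonicity enforcement, via
#' [stats::p.adjust()]) or Bonferroni.
#'
#' @param pvalues numeric vector in `(0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values (same length/order as input).
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = method)
}

#' Genomic inflation factor of a p-value set
#'
#' `lambda_GC = median(chisq_1 quantile of 1 - p) / 0.4549` (the median of a
#' central chi-square with 1 df, `qchisq(0.5, 1) = 0.4549364`). Calibrated
#' tests give `lambda ~ 1`.
#'
#' @param pvalues numeric vector in `(0, 1]`.
#' @return object of class `inflation_report`: `lambda_gc`, `n_pvalues`.
#' @export
genomic_inflation <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chi <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  structure(list(lambda_gc = median(chi) / qchisq(0.5, df = 1),
                 n_pvalues = length(pvalues)),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("Genomic inflation lambda_GC = %.3f (%d p-values)\n",
              x$lambda_gc, x$n_pvalues))
  invisible(x)
}

#' Flag significant results at an FDR threshold
#'
#' @param meta_results table with a `pvalue` column (a `qvalue` column is
#'   added via BH if absent).
#' @param fdr FDR threshold (default 0.10).
#' @return the table with `qvalue` and logical `significant` columns;
#'   attribute `n_significant` holds the call count.
#' @export
call_significant <- function(meta_results, fdr = 0.10) {
  x <- as_dt(meta_results)
  require_cols(x, "pvalue", "result table")
  if (!"qvalue" %in% names(x)) x[, qvalue := adjust_pvalues(pvalue)]
  x[, significant := qvalue < fdr]
  setattr(x, "n_significant", sum(x$significant))
  x[]
}
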