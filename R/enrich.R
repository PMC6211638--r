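# Annotation enrichment by Fisher's exact test, the motif-direction analysis,
# and the ASE x ASB overlap test.

#' Fisher's exact test on a 2x2 annotation/significance table
#'
#' Rows: annotated / not annotated; columns: significant / not significant.
#' Reports the conditional maximum-likelihood odds ratio with its exact 95%
#' CI (the exact-test convention) alongside the sample cross-product ratio.
#'
#' @param a,b,c,d cell counts: `a` annotated & significant, `b` annotated &
#'   not, `c` significant & not annotated, `d` neither.
#' @param name annotation label carried into the result.
#' @return one-row `data.table`: `annotation`, `a`, `b`, `c`, `d`,
#'   `odds_ratio` (conditional MLE), `or_sample`, `ci95_low`, `ci95_high`,
#'   `pvalue`.
#' @export
#' @examples
#' fisher_table(10, 10, 10, 10)$odds_ratio # 1
fisher_table <- function(a, b, c, d, name = "annotation") {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty contingency table", call. = FALSE)
  # rows annotated yes/no, columns significant yes/no
  ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  or_sample <- (a * d) / (b * c)
  data.table(
    annotation = name, a = a, b = b, c = c, d = d,
    odds_ratio = unname(ft$estimate), or_sample = or_sample,
    ci95_low = ft$conf.int[1], ci95_high = ft$conf.int[2],
    pvalue = min(1, ft$p.value) # guard summation overshoot above 1
  )
}

#' Annotation enrichment of a significant set within a universe
#'
#' Builds the 2x2 table of annotation membership against significance over
#' the given universe and applies [fisher_table()].
#'
#' @param significant_set,annotation_set character vectors of ids; both must
#'   be subsets of `universe`.
#' @param universe character vector of all tested ids.
#' @param name annotation label.
#' @return one-row `data.table` as in [fisher_table()].
#' @export
fisher_enrichment <- function(significant_set, annotation_set, universe,
                              name = "annotation") {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  sig <- unique(significant_set)
  ann <- unique(annotation_set)
  if (!all(sig %in% universe)) {
    stop("significant set is not a subset of the universe", call. = FALSE)
  }
  if (!all(ann %in% universe)) {
    stop("annotation set is not a subset of the universe", call. = FALSE)
  }
  in_sig <- universe %in% sig
  in_ann <- universe %in% ann
  fisher_table(sum(in_ann & in_sig), sum(in_ann & !in_sig),
               sum(!in_ann & in_sig), sum(!in_ann & !in_sig), name = name)
}

#' Classify oligo orientation against motif strand
#'
#' Convention: configuration is `"match"` when the motif strand equals the
#' oligo's transcribed strand — forward-orientation oligos transcribe the `+`
#' strand, reverse-orientation oligos the `-` strand — and `"opposite"`
#' otherwise:
#'
#' ```
#'   reporter >>>>  insert + strand >>>>    fwd oligo, motif on "+"  = match
#'   reporter >>>>  insert - strand <<<<    fwd oligo, motif on "-"  = opposite
#' ```
#'
#' @param orientation `"fwd"` / `"rev"`.
#' @param motif_strand `"+"` / `"-"`.
#' @return character vector `"match"` / `"opposite"` (`NA` where the strand
#'   is missing).
#' @export
direction_configuration <- function(orientation, motif_strand) {
  ifelse(is.na(motif_strand) | is.na(orientation), NA_character_,
         ifelse((orientation == "fwd") == (motif_strand == "+"),
                "match", "opposite"))
}

#' Motif-direction enrichment analysis
#'
#' For each transcription factor: a 2x2 table of per-oligo ASE significance
#' against the oligo/motif configuration (match vs opposite, see
#' [direction_configuration()]), tested by Fisher's exact test with
#' Bonferroni correction over the factors tested. A factor with fewer than
#' `min_per_config` oligos in either configuration is skipped with a warning
#' (degenerate margin).
#'
#' @param ase_results per-oligo table with `snp_id`, `orientation` and either
#'   a logical `significant` column or a `qvalue` column (thresholded at
#'   `sig_fdr`).
#' @param design design table with `snp_id`, `motif_factor`, `motif_strand`.
#' @param sig_fdr FDR threshold used when deriving `significant` from
#'   `qvalue` (default 0.10).
#' @param alpha Bonferroni-adjusted significance threshold for flagging a
#'   factor (default 0.05).
#' @param min_per_config minimum oligos per configuration (default 2).
#' @return `data.table`: one row per tested factor with the [fisher_table()]
#'   columns plus `adjusted_pvalue` (Bonferroni) and `flagged`.
#' @export
direction_analysis <- function(ase_results, design, sig_fdr = 0.10,
                               alpha = 0.05, min_per_config = 2) {
  x <- as_dt(ase_results)
  require_cols(x, c("snp_id", "orientation"), "per-oligo ASE table")
  if (!"significant" %in% names(x)) {
    require_cols(x, "qvalue", "per-oligo ASE table")
    x[, significant := qvalue < sig_fdr]
  }
  d <- as_dt(design)
  require_cols(d, c("snp_id", "motif_factor", "motif_strand"), "design table")
  m <- merge(x, d[, .(snp_id, motif_factor, motif_strand)], by = "snp_id")
  m <- m[!is.na(motif_factor)]
  m[, configuration := direction_configuration(orientation, motif_strand)]
  m <- m[!is.na(configuration)]

  out <- list()
  for (f in sort(unique(m$motif_factor))) {
    sub <- m[motif_factor == f]
    n_cfg <- table(factor(sub$configuration, c("match", "opposite")))
    if (any(n_cfg < min_per_config)) {
      warning(sprintf("factor %s skipped: < %d oligos in a configuration",
                      f, min_per_config))
      next
    }
    a <- sub[configuration == "opposite" & significant == TRUE, .N]
    b <- sub[configuration == "opposite" & significant == FALSE, .N]
    cc <- sub[configuration == "match" & significant == TRUE, .N]
    dd <- sub[configuration == "match" & significant == FALSE, .N]
    out[[f]] <- fisher_table(a, b, cc, dd, name = f)
  }
  if (length(out) == 0L) {
    return(data.table(annotation = character(0)))
  }
  res <- rbindlist(out)
  res[, adjusted_pvalue := adjust_pvalues(pvalue, "bonferroni")]
  res[, flagged := adjusted_pvalue < alpha]
  res[]
}

#' Overlap enrichment between ASE and ASB call sets
#'
#' Fisher's exact enrichment of ASB calls among ASE calls over the universe
#' of SNPs testable in both assays. The universe restriction matters:
#' enrichment over the jointly-testable universe generally differs from the
#' same computed over the full design.
#'
#' @param ase_calls,asb_calls character vectors of called SNP ids.
#' @param universe SNPs testable in both assays.
#' @return one-row `data.table` as [fisher_table()], plus `n_overlap`.
#' @export
overlap_ase_asb <- function(ase_calls, asb_calls, universe) {
  res <- fisher_enrichment(intersect(ase_calls, universe),
                           intersect(asb_calls, universe),
                           universe, name = "ASE_x_ASB")
  res[, n_overlap := a]
  res[]
}

adjusted_pvalue <- flagged <- n_overlap <- a <- NULL
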