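# UMI collapse and aggregation of molecule records into allele counts.

#' Collapse PCR duplicates by UMI
#'
#' Within each `(snp_id, orientation, allele, replicate, fraction)` group,
#' reads sharing an identical UMI count as a single molecule; the returned
#' allele counts are the number of distinct UMIs per group (exact-match
#' collapse, no edit-distance clustering).
#'
#' @param records molecule records: `snp_id`, `orientation`, `allele`
#'   (`"ref"`/`"alt"`), `umi` (ACGT string or integer code), `replicate`,
#'   `fraction`.
#' @return allele counts: `snp_id`, `orientation`, `replicate`, `fraction`,
#'   `ref_count`, `alt_count`.
#' @export
#' @examples
#' recs <- data.frame(snp_id = "s1", orientation = "fwd",
#'                    allele = c("ref", "ref", "ref", "alt"),
#'                    umi = c("AAA", "AAT", "AAA", "AAA"),
#'                    replicate = 1L, fraction = "RNA")
#' dedup_umi(recs) # ref_count 2 (distinct UMIs), alt_count 1
dedup_umi <- function(records) {
  # read-only on the hot path: avoid copying what may be tens of millions of
  # rows
  x <- if (is.data.table(records)) records else as.data.table(records)
  require_cols(x, c("snp_id", "allele", "umi", "replicate", "fraction"),
               "molecule table")
  if (!"orientation" %in% names(x)) {
    x <- copy(x)[, orientation := "pooled"]
  }
  if (is.character(x$umi)) {
    len <- unique(nchar(x$umi))
    if (length(len) > 1L) {
      stop("molecule table mixes UMI lengths: ",
           paste(len, collapse = ", "), call. = FALSE)
    }
    if (any(grepl("[^ACGT]", x$umi))) {
      stop("UMIs contain characters outside {A,C,G,T}", call. = FALSE)
    }
  }
  mol <- unique(x, by = c("snp_id", "orientation", "allele", "umi",
                          "replicate", "fraction"))
  counts_from_molecules(mol)
}

#' Count reads without UMI collapse
#'
#' The duplicate-retaining counterpart of [dedup_umi()]: every read counts.
#' Used by the duplicate-retention ablation of the pipeline.
#'
#' @inheritParams dedup_umi
#' @return allele counts in the same shape as [dedup_umi()].
#' @export
count_reads <- function(records) {
  x <- if (is.data.table(records)) records else as.data.table(records)
  require_cols(x, c("snp_id", "allele", "replicate", "fraction"),
               "molecule table")
  if (!"orientation" %in% names(x)) {
    x <- copy(x)[, orientation := "pooled"]
  }
  counts_from_molecules(x)
}

counts_from_molecules <- function(mol) {
  cnt <- mol[, .N, by = .(snp_id, orientation, allele, replicate, fraction)]
  wide <- dcast(cnt, snp_id + orientation + replicate + fraction ~ allele,
                value.var = "N", fill = 0L)
  for (al in c("ref", "alt")) if (!al %in% names(wide)) wide[, (al) := 0L]
  setnames(wide, c("ref", "alt"), c("ref_count", "alt_count"))
  setcolorder(wide, c("snp_id", "orientation", "replicate", "fraction",
                      "ref_count", "alt_count"))
  wide[]
}

#' Aggregate allele counts over orientations and/or replicates
#'
#' @param counts an allele-count table.
#' @param pool_orientation sum the two oligo orientations? (default `TRUE`;
#'   the allelic tests run on pooled counts, the motif-direction analysis on
#'   stratified ones).
#' @param pool_replicates sum replicates as well? (default `FALSE`)
#' @return aggregated allele counts.
#' @export
aggregate_counts <- function(counts, pool_orientation = TRUE,
                             pool_replicates = FALSE) {
  x <- as_dt(counts)
  require_cols(x, c("snp_id", "ref_count", "alt_count"), "count table")
  keys <- id_cols_of(x)
  if (pool_orientation) keys <- setdiff(keys, "orientation")
  if (pool_replicates) keys <- setdiff(keys, "replicate")
  x[, .(ref_count = sum(ref_count), alt_count = sum(alt_count)), by = keys]
}

#' Estimate per-SNP plasmid DNA reference proportions
#'
#' Pools ref/alt counts across DNA replicates (and orientations) and applies
#' a Haldane–Anscombe pseudocount so the proportion stays off the boundary:
#' `p0 = (Dref + c) / (Dref + Dalt + 2c)`, with binomial sampling variance
#' `var0 = p0 (1 - p0) / (Dref + Dalt + 2c)`.
#'
#' SNPs absent from the DNA library (zero pooled molecules) are excluded and
#' reported via the `"untestable"` attribute rather than raising an error.
#'
#' @param dna_counts DNA allele-count table.
#' @param pseudocount pseudocount `c` (default 0.5).
#' @return `data.table` with `snp_id`, `p0`, `var0`, `d_total`; attribute
#'   `untestable` lists excluded SNP ids.
#' @export
estimate_dna_proportion <- function(dna_counts, pseudocount = 0.5) {
  x <- aggregate_counts(dna_counts, pool_orientation = TRUE,
                        pool_replicates = TRUE)
  pooled <- x[, .(Dref = sum(ref_count), Dtot = sum(ref_count + alt_count)),
              by = snp_id]
  bad <- pooled[Dtot == 0L, snp_id]
  ok <- pooled[Dtot > 0L]
  res <- ok[, {
    p <- (Dref + pseudocount) / (Dtot + 2 * pseudocount)
    .(p0 = p, var0 = p * (1 - p) / (Dtot + 2 * pseudocount), d_total = Dtot)
  }, by = snp_id]
  setattr(res, "untestable", bad)
  res[]
}

#' Filter SNPs testable for allelic imbalance
#'
#' Retains SNPs whose pooled RNA molecule total and pooled DNA molecule total
#' meet the thresholds. The exact filter used on the original data is not
#' published; the defaults (RNA >= 5, DNA >= 10 deduplicated molecules) are
#' deliberately conservative and exposed.
#'
#' @param rna_counts RNA allele-count table.
#' @param dna_counts DNA allele-count table.
#' @param min_rna_total,min_dna_total pooled-molecule thresholds.
#' @return list with `rna` and `dna` (filtered tables restricted to testable
#'   SNPs) and `summary` (`data.table` of drop reasons and counts).
#' @export
filter_testable <- function(rna_counts, dna_counts,
                            min_rna_total = 5, min_dna_total = 10) {
  rna <- as_dt(rna_counts)
  dna <- as_dt(dna_counts)
  rna_tot <- rna[, .(tot = sum(ref_count + alt_count)), by = snp_id]
  dna_tot <- dna[, .(tot = sum(ref_count + alt_count)), by = snp_id]
  all_ids <- union(rna_tot$snp_id, dna_tot$snp_id)
  rna_ok <- rna_tot[tot >= min_rna_total, snp_id]
  dna_ok <- dna_tot[tot >= min_dna_total, snp_id]
  keep <- intersect(rna_ok, dna_ok)
  summary <- data.table(
    reason = c("tested", "low_rna", "low_dna"),
    n_snps = c(length(keep),
               length(setdiff(all_ids, rna_ok)),
               length(setdiff(all_ids, dna_ok)))
  )
  list(rna = rna[snp_id %in% keep],
       dna = dna[snp_id %in% keep],
       summary = summary)
}

Dref <- Dtot <- tot <- NULL # data.table NSE bindings
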