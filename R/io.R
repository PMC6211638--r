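# Table readers/writers (TSV interchange), UMI string/integer conversion,
# oligo FASTA emission, QQ reporting.

#' Convert integer UMI codes to ACGT strings (and back)
#'
#' UMIs are base-4 codes: the most significant digit is the first base, with
#' `A=0, C=1, G=2, T=3`.
#'
#' @param x integer codes in `[0, 4^umi_length)`.
#' @param umi_length UMI length in bases.
#' @return character vector of ACGT strings.
#' @export
umi_int_to_string <- function(x, umi_length) {
  bases <- c("A", "C", "G", "T")
  x <- as.numeric(x)
  if (any(x < 0 | x >= 4^umi_length)) {
    stop("UMI code out of range for the given length", call. = FALSE)
  }
  digits <- matrix("", nrow = length(x), ncol = umi_length)
  rem <- x
  for (pos in umi_length:1) {
    digits[, pos] <- bases[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  do.call(paste0, as.data.frame(digits, stringsAsFactors = FALSE))
}

#' @rdname umi_int_to_string
#' @param s character vector of ACGT strings (equal lengths).
#' @export
umi_string_to_int <- function(s) {
  len <- unique(nchar(s))
  if (length(len) != 1L) stop("UMI strings have mixed lengths", call. = FALSE)
  if (any(grepl("[^ACGT]", s))) {
    stop("UMIs contain characters outside {A,C,G,T}", call. = FALSE)
  }
  val <- numeric(length(s))
  for (pos in seq_len(len)) {
    d <- match(substr(s, pos, pos), c("A", "C", "G", "T")) - 1
    val <- val * 4 + d
  }
  val
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- fread(path, sep = "\t", header = TRUE)
  require_cols(x, required, paste0(what, " (", path, ")"))
  x
}

#' Read / write the pipeline's TSV tables
#'
#' All interchange is tab-separated with a header row. `write_molecules()`
#' emits UMIs as ACGT strings (the on-disk contract); `read_molecules()`
#' returns them as integer codes unless `umi_as = "string"`.
#'
#' @param path file path.
#' @param x table to write.
#' @return readers return a `data.table`; writers return `path` invisibly.
#' @name io_tables
NULL

#' @rdname io_tables
#' @param umi_as `"integer"` (default) or `"string"`.
#' @export
read_molecules <- function(path, umi_as = c("integer", "string")) {
  umi_as <- match.arg(umi_as)
  x <- read_table_checked(path, c("snp_id", "orientation", "allele", "umi",
                                  "replicate", "fraction"), "molecule table")
  if (is.character(x$umi) && umi_as == "integer") {
    L <- unique(nchar(x$umi))
    if (length(L) != 1L) stop("molecule table mixes UMI lengths", call. = FALSE)
    x[, umi := umi_string_to_int(umi)]
    setattr(x, "umi_length", as.integer(L))
  }
  x
}

#' @rdname io_tables
#' @param umi_length UMI length (defaults to the table's `umi_length`
#'   attribute) used when converting integer codes to strings.
#' @export
write_molecules <- function(x, path, umi_length = NULL) {
  x <- as_dt(x)
  require_cols(x, c("snp_id", "orientation", "allele", "umi", "replicate",
                    "fraction"), "molecule table")
  if (!is.character(x$umi)) {
    L <- umi_length %||% attr(x, "umi_length")
    if (is.null(L)) stop("umi_length needed to encode integer UMIs",
                         call. = FALSE)
    x[, umi := umi_int_to_string(umi, L)]
  }
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname io_tables
#' @export
read_counts <- function(path) {
  read_table_checked(path, c("snp_id", "replicate", "fraction",
                             "ref_count", "alt_count"), "count table")
}

#' @rdname io_tables
#' @export
read_design <- function(path) {
  read_table_checked(path, c("snp_id", "ref_allele", "alt_allele",
                             "category"), "design table")
}

#' @rdname io_tables
#' @export
read_dna_proportions <- function(path) {
  read_table_checked(path, c("snp_id", "p0", "var0", "d_total"),
                     "DNA proportion table")
}

#' @rdname io_tables
#' @export
write_table_tsv <- function(x, path) {
  fwrite(as_dt(x), path, sep = "\t")
  invisible(path)
}

#' Emit synthetic oligo sequences as FASTA
#'
#' Writes one record per SNP x allele x orientation: a 200 bp regulatory
#' insert with the SNP at the center (position 100, 1-based) flanked by
#' 15 bp constant adapters, 230 bp total. Sequence content away from the SNP
#' is random (no motif or GC realism — the analysis is sequence-free).
#'
#' @param design design table from [simulate_design()].
#' @param path output FASTA path.
#' @param seed RNG seed for the random backbone.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(design, path, seed = 1) {
  d <- as_dt(design)
  require_cols(d, c("snp_id", "ref_allele", "alt_allele"), "design table")
  set.seed(stage_seed(seed, "fasta"))
  bases <- c("A", "C", "G", "T")
  adapter5 <- "ACTGGCCGCTTCACT"
  adapter3 <- "AGATCGGAAGAGCGT"
  con <- file(path, open = "wt")
  on.exit(close(con))
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in seq_len(nrow(d))) {
    backbone <- paste(sample(bases, 200, replace = TRUE), collapse = "")
    for (al in c("ref", "alt")) {
      allele <- if (al == "ref") d$ref_allele[i] else d$alt_allele[i]
      insert <- paste0(substr(backbone, 1, 99), allele,
                       substr(backbone, 101, 200))
      for (or in c("fwd", "rev")) {
        seq_or <- if (or == "fwd") insert else revcomp(insert)
        writeLines(c(
          sprintf(">%s|%s|%s", d$snp_id[i], al, or),
          paste0(adapter5, seq_or, adapter3)
        ), con)
      }
    }
  }
  invisible(path)
}

#' QQ report for p-value sets
#'
#' Observed vs expected -log10 p-value quantiles, optionally stratified.
#' Returns both the underlying table (for testing) and a ggplot.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param strata optional labels (same length) splitting the p-values into
#'   strata plotted separately.
#' @return list with `table` (`stratum`, `expected`, `observed` on the
#'   -log10 scale) and `plot` (a ggplot object).
#' @export
qq_report <- function(pvalues, strata = NULL) {
  if (length(pvalues) == 0L) stop("no p-values", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  st <- strata %||% rep("all", length(pvalues))
  stopifnot(length(st) == length(pvalues))
  dt <- data.table(pvalue = pvalues, stratum = as.character(st))
  tab <- dt[order(pvalue), {
    n <- .N
    .(expected = -log10((seq_len(n) - 0.5) / n),
      observed = -log10(sort(pvalue)))
  }, by = stratum]
  plt <- ggplot2::ggplot(tab, ggplot2::aes(x = expected, y = observed,
                                           colour = stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p)))) +
    ggplot2::theme_minimal()
  list(table = tab[], plot = plt)
}
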