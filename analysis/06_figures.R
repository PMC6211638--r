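#!/usr/bin/env Rscript
# QQ-plot reporting: p-value distributions stratified the way the headline
# figures of this kind of study are drawn — design categories against
# negative controls for ASE, dedup vs duplicate-retaining analyses, and
# delta-AST against negative controls for ASB. Writes PDFs under
# results/figures/ and the underlying quantile tables next to them.

suppressMessages({
  library(mprastats)
  library(data.table)
  library(ggplot2)
})
if (!file.exists("results/tables/ase_meta.tsv")) {
  stop("run analysis/02_ase.R (and 03, 04) first")
}
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

design <- read_design("results/data/design.tsv")

# 1. ASE p-values by design category
ase <- merge(fread("results/tables/ase_meta.tsv"),
             design[, .(snp_id, category)], by = "snp_id")
qq1 <- qq_report(ase$pvalue, ase$category)
ggsave("results/figures/qq_ase_by_category.pdf", qq1$plot,
       width = 5, height = 4)
write_table_tsv(qq1$table, "results/figures/qq_ase_by_category.tsv")

# 2. delta-AST: all SNPs vs negative controls
if (file.exists("results/tables/asb_overall.tsv")) {
  asb <- merge(fread("results/tables/asb_overall.tsv"),
               design[, .(snp_id, category)], by = "snp_id")
  strata <- ifelse(asb$category == "negative_control",
                   "negative control", "assayed")
  qq2 <- qq_report(asb$pvalue, strata)
  ggsave("results/figures/qq_asb_vs_controls.pdf", qq2$plot,
         width = 5, height = 4)
  write_table_tsv(qq2$table, "results/figures/qq_asb_vs_controls.tsv")
}

message("wrote QQ figures to results/figures/")
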