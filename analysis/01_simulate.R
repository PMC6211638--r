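#!/usr/bin/env Rscript
# Generate the study-scale synthetic dataset the downstream analyses consume:
# 10,000 biallelic SNPs in four design categories, a 7-replicate plasmid DNA
# library with Beta-distributed allele imbalance, 9 RNA replicates with
# beta-binomial overdispersion and UMI-tagged PCR duplicates, and
# bound/unbound binding fractions in triplicate at three protein
# concentrations. Writes TSV tables under results/data/.

suppressMessages({
  library(mprastats)
  library(data.table)
})

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_snps = 10000, seed = 20260929)
message("simulating design and truth (n = ", cfg$n_snps, ") ...")
d <- simulate_design(cfg)

message("simulating DNA, RNA and binding counts ...")
dna <- simulate_dna_counts(d$design, d$truth, cfg)
rna <- simulate_rna_counts(d$design, d$truth, cfg)
binding <- simulate_binding_counts(d$design, d$truth, cfg)

write_table_tsv(d$design, file.path(out_dir, "design.tsv"))
write_table_tsv(d$truth, file.path(out_dir, "truth.tsv"))
write_table_tsv(dna, file.path(out_dir, "dna_counts.tsv"))
write_table_tsv(rna, file.path(out_dir, "rna_counts.tsv"))
write_table_tsv(binding$allele, file.path(out_dir, "binding_allele_counts.tsv"))
write_table_tsv(binding$region, file.path(out_dir, "binding_region_counts.tsv"))

# Molecule-level records (with UMIs and PCR duplicates) are bulky; write an
# illustrative 300-SNP subsample. The duplicate-retention analysis in
# 03_umi_ablation.R regenerates molecules in memory at full scale instead.
sub_ids <- d$design$snp_id[seq_len(300)]
mol <- simulate_rna_molecules(d$design[snp_id %in% sub_ids],
                              d$truth[snp_id %in% sub_ids], cfg)
write_molecules(mol, file.path(out_dir, "rna_molecules_subsample.tsv"))

write_oligo_fasta(d$design[seq_len(50)], file.path(out_dir, "oligos_subsample.fa"),
                  seed = cfg$seed)

cfg_out <- cfg
cfg_out$motif_factors <- paste(cfg_out$motif_factors, collapse = ",")
write_table_tsv(as.data.table(cfg_out[!vapply(cfg_out, is.null, logical(1))]),
                file.path(out_dir, "sim_config.tsv"))

message("wrote ", length(list.files(out_dir)), " files to ", out_dir)
message(sprintf("  %d SNPs, %d truly functional (ASE), %d with binding effects",
                cfg$n_snps, sum(d$truth$beta_true != 0),
                sum(d$truth$gamma_true != 0)))
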