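#!/usr/bin/env Rscript
# Step 1: generate the synthetic binding study.
#
# Emits a genome with motif-planted promoters, a TSS annotation, two
# replicate peak-call tables and the ground-truth plant ledger under
# results/data/. The study is shaped like a genome-wide corepressor ChIP
# experiment: 1236 peaks shared between the replicates plus 951 and 101
# replicate-specific calls, summits centred 205 bp upstream of the TSS, and
# four promoter motifs planted at higher frequency on bound promoters
# (except the Forkhead-family motif, planted evenly — a generally
# distributed element).

suppressPackageStartupMessages(library(regulonscan))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(
  n_chroms = 4, chrom_length = 4e6, n_genes = 3600,
  n_shared_peaks = 1236, n_unique_rep1 = 951, n_unique_rep2 = 101,
  summit_jitter_sd = 30, summit_tss_offset_mean = -205,
  summit_tss_offset_sd = 100, seed = 424243)
print(cfg)

pwms <- synthetic_motifs()
study <- simulate_study(cfg, pwms)

Biostrings::writeXStringSet(study$genome, "results/data/genome.fa")
write_tss(study$tss, "results/data/tss.bed", format = "bed")
write_peaks(study$rep1, "results/data/rep1_peaks.tsv")
write_peaks(study$rep2, "results/data/rep2_peaks.tsv")
write.table(study$ledger, "results/data/plant_ledger.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_pwms_meme(pwms, "results/data/motifs.meme")

cat(sprintf(
  "genome: %d chromosomes x %g bp; %d genes\n",
  length(study$genome), cfg$chrom_length, nrow(study$tss)))
cat(sprintf("replicate 1: %d peaks; replicate 2: %d peaks\n",
            nrow(study$rep1), nrow(study$rep2)))
cat(sprintf("planted motif instances: %d on bound promoters, %d elsewhere\n",
            sum(study$ledger$bound), sum(!study$ledger$bound)))
cat("wrote results/data/{genome.fa,tss.bed,rep[12]_peaks.tsv,plant_ledger.tsv,motifs.meme}\n")
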