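#!/usr/bin/env Rscript
# Step 5: motif composition of the bound regions.
#
# Three views: (i) constellation counts — which exact subset of the motif
# panel each peak carries; (ii) per-motif enrichment of the bound regions
# against five sets of 1000 unbound promoters (window -300..-100 relative to
# the TSS); (iii) per-category motif fractions over the peak-assigned genes,
# using a synthetic gene-category map.

suppressPackageStartupMessages(library(regulonscan))

pwms <- read_pwms_meme("results/data/motifs.meme")
regions <- Biostrings::readDNAStringSet("results/class_a_regions.fa")
thr <- read.table("results/chosen_thresholds.tsv", header = TRUE, sep = "\t")
thresholds <- setNames(thr$threshold, thr$motif_id)
pm_tab <- read.table("results/motif_presence.tsv", header = TRUE, sep = "\t")
pm <- structure(as.matrix(pm_tab[, -1]) == 1,
                dimnames = list(pm_tab$region_id, colnames(pm_tab)[-1]),
                scorable = rep(TRUE, nrow(pm_tab)),
                class = c("motif_presence", "matrix"))

## (i) constellations
cc <- constellation_counts(pm)
print(cc)
write.table(data.frame(constellation = names(cc$counts),
                       n_regions = as.integer(cc$counts)),
            "results/constellations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## (ii) enrichment vs unbound promoters
genome <- Biostrings::readDNAStringSet("results/data/genome.fa")
ann <- read_tss("results/data/tss.bed")
links <- read.table("results/peak_gene_links.tsv", header = TRUE, sep = "\t")
# "unbound" = no peak of any class within the assignment window, so the pool
# excludes replicate-specific (Class B/C) binding as well
cls <- read.table("results/classification.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
all_peaks <- peak_set(cls[, c("peak_id", "chrom", "start", "end", "summit",
                              "intensity")], replicate_id = "all")
near_any <- assign_peaks_to_tss(all_peaks, ann, window = 2000)
unbound <- ann[!ann$gene_id %in% near_any$links$gene_id, , drop = FALSE]
pool <- extract_promoter_windows(genome, unbound)
er <- background_promoter_enrichment(pwms, regions, pool,
                                     thresholds = thresholds,
                                     n_sets = 5, set_size = 1000,
                                     seed = 515099)
print(er)
write.table(er$table, "results/motif_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## (iii) per-category motif fractions
asn <- structure(list(links = links, window = 2000,
                      n_peaks = length(unique(links$peak_id)),
                      unassigned = character(0)),
                 class = "peak_gene_assignment")
cats <- simulate_gene_categories(unique(links$gene_id), n_categories = 8,
                                 seed = 515123)
tab <- category_motif_fractions(asn, pm, cats)
print(tab)
out <- data.frame(category = rownames(tab$fractions), tab$fractions,
                  n_genes = tab$gene_counts, check.names = FALSE)
write.table(out, "results/category_motif_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cats, "results/data/gene_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("wrote results/{constellations,motif_enrichment,category_motif_fractions}.tsv\n")
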