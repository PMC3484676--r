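#!/usr/bin/env Rscript
# Step 6: cross-species regulon overlap.
#
# Maps the peak-assigned (target) genes to synthetic human ortholog families,
# intersects the ortholog set with per-condition bound-gene sets for two
# human corepressor factors, computes Venn partitions for the three
# RB-factor conditions, and tests category enrichment of the conserved
# subset with a hypergeometric model and BH correction.

suppressPackageStartupMessages(library(regulonscan))

links <- read.table("results/peak_gene_links.tsv", header = TRUE, sep = "\t")
targets <- unique(links$gene_id)

omap <- simulate_ortholog_map(targets, seed = 616001)
write.table(as.data.frame(omap), "results/data/ortholog_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
m2h <- map_fly_to_human(targets, omap)
cat(sprintf("%d target genes -> %d human orthologs (%d unmapped)\n",
            length(targets), length(m2h$human_genes), length(m2h$unmapped)))

conds <- simulate_condition_sets(m2h$human_genes, seed = 616002)
long <- do.call(rbind, lapply(names(conds), function(cn)
  data.frame(condition = cn, gene_id = conds[[cn]])))
write.table(long, "results/data/condition_sets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ot <- overlap_table(m2h$human_genes, conds)
print(ot)
write.table(ot, "results/condition_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

vp <- venn_partition(c(list(orthologs = m2h$human_genes),
                       conds[c("RB_growing", "RB_quiescent",
                               "RB_senescent")]))
write.table(vp, "results/venn_rb_conditions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rb_any <- unique(unlist(conds[startsWith(names(conds), "RB")]))
fams <- family_bound_in_both(targets, rb_any, omap)
cat(sprintf("families bound in both species (any RB condition): %d of %d\n",
            length(fams), length(unique(omap$family_id))))

conserved <- intersect(m2h$human_genes, rb_any)
hcats <- simulate_gene_categories(m2h$human_genes, n_categories = 8,
                                  seed = 616003)
enr <- category_enrichment(conserved, m2h$human_genes, hcats)
print(enr, digits = 3)
write.table(enr, "results/conserved_category_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("wrote results/{condition_overlap,venn_rb_conditions,conserved_category_enrichment}.tsv\n")
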