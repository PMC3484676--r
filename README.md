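# regulonscan

Downstream analysis of genome-wide transcription-cofactor binding from
replicated ChIP-seq peak calls. The package is written for regulatory
genomicists who have two replicate peak lists, a genome, a set of candidate
promoter motifs, and annotation tables, and who want the classical
promoter-proximal regulon analysis chain as tested, reusable functions:

1. **Replicate reconciliation** — peaks whose summits lie within 200 bp
   across replicates are matched one-to-one (greedy by ascending summit
   distance) into concordant **Class A** peaks; the rest stay **Class B**
   (replicate 1 only) or **Class C** (replicate 2 only). The accounting is
   exact: |A| + |B| = |rep1| and |A| + |C| = |rep2|.
2. **Promoter-proximal annotation** — each peak links to every TSS within
   2 kb of its summit, with signed strand-aware distances (negative =
   upstream); a smoothed 100-bp histogram locates the summit-bias mode, and
   the intensity summary counts >10x-median outliers.
3. **Calibrated motif scanning** — PWM log-odds scores
   `sum_i log2(p_i(b_i)/q(b_i))` with the *exact* single-window null
   computed by column-wise convolution; a per-sequence best-hit p-value
   `p = 1 - (1 - p_site)^m` (Sidak over the `m` scorable windows, both
   strands); the presence threshold per motif is calibrated by scrambling
   the regions five times and choosing the candidate (decades 1e-2..1e-6)
   that maximizes the real-minus-scrambled call-rate difference.
4. **Composition profiling** — per-peak motif constellations, enrichment of
   bound regions against five sets of 1000 unbound promoters
   (window TSS-300..TSS-100), and per-category motif-fraction tables.
5. **Regulon conservation** — fly-to-human ortholog families (connected
   components of the link graph), the at-least-one-member-per-species
   bound-in-both rule, per-condition overlaps and Venn partitions, and
   hypergeometric category enrichment with Benjamini-Hochberg correction.

A synthetic-data generator (`synthetic_config()` / `simulate_study()`)
emits genomes, annotations, replicate peak lists and motif-planted
promoters with complete ground truth, so the whole chain is testable
without external data. The bundled motif panel
(`inst/extdata/synthetic_motifs.meme`) is illustrative and synthetic.

## Worked example

```r
library(regulonscan)

pwms <- synthetic_motifs()
cfg <- synthetic_config(n_chroms = 2, chrom_length = 2e6, n_genes = 900,
                        n_shared_peaks = 400, n_unique_rep1 = 80,
                        n_unique_rep2 = 30, seed = 7)
study <- simulate_study(cfg, pwms)

cl <- classify_replicates(study$rep1, study$rep2, max_dist = 200)
#> peak_classification (max_dist = 200 bp): 400 Class A pairs, 80 Class B, 30 Class C

asn <- assign_peaks_to_tss(cl$class_a, study$tss, window = 2000)
#> peak_gene_assignment (window 2000 bp): 400 links, 400/400 peaks assigned to 400 genes

regions <- extract_peak_sequences(study$genome, cl$class_a)
calibrate_threshold(pwms$RAM, regions, seed = 1)
#> calibration for 'RAM' (400 regions, 5 scrambles):
#>  threshold frac_bound frac_scrambled difference
#>      1e-02     0.1275         0.0125      0.115
#>      1e-03     0.1175         0.0015      0.116
#>      1e-04     0.0625         0.0005      0.062
#>      1e-05     0.0000         0.0000      0.000
#>      1e-06     0.0000         0.0000      0.000
#> chosen threshold: 0.001

pm <- scan_regions(pwms, regions,
                   c(E2F = 1e-2, DREF = 1e-2, FOXJ2 = 1e-2, RAM = 1e-3))
constellation_counts(pm)
#> constellations over 400 regions:
#>   0 motif(s): 284 (71.0%)
#>   1 motif(s): 101 (25.2%)
#>   2 motif(s): 14 (3.5%)
#>   3 motif(s): 1 (0.2%)
#>   4 motif(s): 0 (0.0%)
```

Reading the numbers: all 400 shared peaks are recovered as Class A (the
jitter SD of 30 bp keeps replicate summits well inside 200 bp) and every
Class A peak finds its anchor TSS within 2 kb. The calibration table shows
the novel-motif scramble null: at 1e-2 about 1% of scrambled regions are
called (chance), at 1e-3 the chance calls vanish while the planted-motif
calls remain, so 1e-3 maximizes the difference — with exact-consensus
plants the optimum moves to the canonical 1e-4. The constellation
partition (it always sums to the region count) reflects the planting
frequencies after mismatch noise and peak/promoter window overlap.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # genome, TSS, replicate peaks, ledger
Rscript analysis/02_classify_peaks.R  # Class A/B/C + 200-bp region FASTA
Rscript analysis/03_annotate_peaks.R  # links, distance histogram, intensities
Rscript analysis/04_motif_calibration.R  # scramble calibration + presence
Rscript analysis/05_enrichment.R      # constellations, enrichment, categories
Rscript analysis/06_conservation.R    # orthologs, overlaps, Venn, enrichment
```

Each step prints what it found and is a thin narrative over the package
functions, so any stage can be re-run interactively.

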