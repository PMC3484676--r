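---
title: "Methods: replicate peak reconciliation, calibrated motif scanning, and regulon conservation"
author: "regulonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate peak reconciliation, calibrated motif scanning, and regulon conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

# Scope

`regulonscan` implements the downstream analysis chain for a genome-wide
ChIP-seq study of a promoter-proximal transcriptional corepressor performed
in two biological replicates:

1. **Replicate reconciliation** — merging two peak-call lists into
   concordant (Class A) and replicate-specific (Class B/C) peaks by summit
   distance.
2. **Promoter-proximal annotation** — linking peaks to transcription start
   sites (TSSs) within a fixed window and summarizing the signed
   summit-to-TSS distances and peak intensities.
3. **Motif scanning** — position-weight-matrix (PWM) scoring with exact
   null distributions, a per-sequence best-hit p-value, and a significance
   threshold calibrated against composition-preserving scrambles.
4. **Composition profiling** — motif constellations per peak, enrichment of
   bound regions against unbound-promoter backgrounds, and per-category
   motif fractions.
5. **Regulon conservation** — mapping target genes to another species
   through ortholog families and measuring per-condition binding overlap
   with hypergeometric category enrichment.

Upstream steps (read alignment, peak calling, de novo motif discovery,
GO annotation, ortholog database lookup) are out of scope: peak tables,
PWMs, category maps and ortholog maps are *inputs*. A synthetic-data
generator with complete ground truth stands in for the unavailable raw
data, so every stage is testable end to end.

# Replicate reconciliation

A peak is identified by its **summit** (the coordinate of maximum signal).
Two peaks from different replicates match when they lie on the same
chromosome with summit distance at most `max_dist` (default **200 bp**).
Matching is **one-to-one and greedy by ascending distance**, with ties
broken by the lower replicate-1 summit, then the lower replicate-2 summit.

One-to-one matching is a deliberate choice: nearest-neighbour matching with
reuse could attach two replicate-1 peaks to one replicate-2 peak, breaking
the additive accounting that the classification is for. With one-to-one
matching the partition identities

\[ |A| + |B| = |\mathrm{rep1}|, \qquad |A| + |C| = |\mathrm{rep2}| \]

hold on every input, and the test suite checks them property-style on
thousands of random instances, along with agreement against a brute-force
matcher on instances of up to 50 peaks. How multi-way ambiguities are
resolved is not observable from class counts alone; the greedy rule is this
package's documented convention.

Class A pairs are represented by their replicate-1 member (summit and
intensity), reflecting the stronger first replicate in the motivating
design. The 200-bp region `[summit - 100, summit + 100)` of each Class A
peak is the unit of all sequence analysis.

# Promoter-proximal annotation

A peak links to **every** gene whose TSS lies within `window` bp of its
summit (default **2000 bp, inclusive**: "within 2 kb" is read as a closed
interval, and the boundary is tested explicitly). Distances are signed and
strand-aware: negative means the summit is upstream of the TSS in the
gene's transcription direction. The assignment also records, per peak, the
single nearest TSS, so both "any TSS within the window" and "nearest TSS"
counts are available.

The distance histogram uses **100-bp bins** over `[-window, window]`. The
counts are smoothed with a centred kernel before the mode is reported; the
default kernel is **triangular** (discrete binomial weights, 1/4–1/2–1/4 at
the default span of 3 bins) rather than a flat boxcar. The reason is
numerical: when the offset distribution is tighter than one bin (e.g. SD
40 bp against 100-bp bins), a flat window-3 average almost exactly
equalizes the two bins adjacent to the true mode — their smoothed masses
differ only through the far tails — and mode recovery degrades to roughly
chance between the two. The triangular kernel keeps the central bin's own
count dominant while still damping noise, and recovers the planted mode in
>99% of simulations at n = 1000 links. Both kernels are available
(`kernel = "boxcar"` restores the flat average), and ties in the smoothed
maximum go to the bin nearer zero.

The intensity summary reports the exact median (lower of the two middle
values for an even count), the max/median ratio, and the number of peaks
exceeding ten times the median — the "few large outliers" diagnostic for
intensity distributions spanning about an order of magnitude.

# Motif model and exact p-values

A PWM is a width × 4 matrix of base probabilities with a positive
background composition; a window scores the summed log2 odds
\(\sum_i \log_2 (p_i(b_i) / q(b_i))\), in bits. Windows containing non-ACGT
characters are *unscorable* and are skipped (never scored as 0).

The null distribution of the single-window score under i.i.d. background
bases is computed **exactly** by column-wise convolution after rounding
each column's log-odds to multiples of `granularity` (default **0.01
bits**). The rounding error of any window score is bounded by
`width * granularity / 2` (at most 0.06 bits for a 12-bp motif); observed
window scores are accumulated from the same rounded columns, so they land
exactly on the null support and the tail lookup is exact, not interpolated.
The test suite verifies the convolution against full `4^w` enumeration for
every bundled motif of width ≤ 8 to within 1e-9.

The **best-hit p-value** of a motif in a sequence is
\(p_{\mathrm{site}} = P(\text{window score} \ge \text{best observed})\)
from the exact null, converted to a sequence-level p-value with a Šidák
correction over the `m` scorable windows on both strands:
\(p = 1 - (1 - p_{\mathrm{site}})^m\), with `m` reduced when windows are
masked by Ns. For informative, non-self-complementary motifs this p-value
is empirically uniform on background sequences (checked with a
Kolmogorov–Smirnov test at n = 2000). Two caveats are intrinsic to the
correction and documented rather than patched:

* **Palindromic motifs** (the bundled DREF-like matrix is a perfect
  palindrome) have fully dependent forward and reverse scores at each
  offset, so counting both strands in `m` makes their p-values
  *conservative* — stochastically large, never anticonservative. The tests
  assert the conservative direction.
* **Overlapping windows** are weakly dependent; the residual effect on the
  false-call rate is small for high-information motifs and is covered by
  the tolerance of the convergence test.

# Scramble calibration

The presence threshold per motif is calibrated exactly as the motivating
design prescribes: the region sequences are scrambled (by default a
**mononucleotide**, composition-preserving permutation; a dinucleotide
Eulerian-path shuffle is available as an option) **five times**, the
fraction of regions called at each candidate threshold is compared between
real and scrambled sequences, and the candidate maximizing the difference
is chosen, ties going to the more stringent value. The candidate grid
spans decade steps **1e-2 … 1e-6** and includes the canonical **1e-4**.

The arithmetic of the Šidák correction explains when 1e-4 wins: in a
200-bp region a perfect 12-bp consensus has
\(p \approx 1 - (1 - 0.25^{12})^{378} \approx 2.3\times10^{-5}\), which
sits between 1e-5 and 1e-4 — so 1e-4 catches every planted consensus while
the scramble false-call rate (≈ t) is negligible, and stricter candidates
lose the signal. Shorter motifs top out at larger p-values (an 8-mer
consensus reaches only ≈ 6e-3), so their calibrated thresholds settle at
1e-2; a 7-mer cannot reach 1e-2 at all in 200-bp regions, which is why the
bundled panel uses widths 8–12. When planted instances carry mismatches
(plant strength < 1), the calibrated threshold relaxes accordingly — the
calibration tracks the actual signal quality, which is its purpose.

# Composition profiling

`scan_regions` produces a boolean regions × motifs presence matrix —
multiple hits of one motif in a region count once. Constellations (the
exact subset of the panel present in each region) partition the scorable
regions; the partition identity is asserted on every output.

Enrichment against unbound promoters follows the 5 × 1000 background
design: five independent samples of 1000 promoters not bound in the study,
scanned over the strand-aware window `[TSS-300, TSS-100)`, give per-motif
background fractions; the report is the ratio of the bound fraction to the
background mean (plus an empirical z-score). No multiple-testing
correction is applied — ratios, not p-values, are the primary output.
Note an asymmetry inherited from the design: bound regions are peak-centred
windows that only partially overlap promoters, while the background is the
promoter window itself, so ratios *understate* the underlying frequency
contrast, and a motif planted at equal frequency on both sides shows a
ratio somewhat below 1 rather than exactly 1.

Per-category motif fractions use ANY-peak semantics: a gene is
motif-positive if any peak assigned to it carries the motif. Each category
row reports the fraction of its assigned genes positive for each motif
plus a "none" column, with an "all" row over every assigned gene;
categories with no assigned genes yield explicit NA rows. Category
definitions arrive as an auditable gene → category table; building them
(e.g. from GO annotation) is out of scope.

# Regulon conservation

Ortholog links (fly gene, human gene) are grouped into **families**: the
connected components of the bipartite link graph when no curated family ids
are supplied. A family counts as **bound in both species** when at least
one fly member and at least one human member are bound — the standard
family-level rule. Per-condition overlaps and Venn partitions (guarded at
five sets) are plain set algebra, tested against bit-vector enumeration.
Category enrichment of a conserved subset uses the **hypergeometric upper
tail** with **Benjamini–Hochberg** correction across categories, plus a
lower-tail p and a depletion flag when the fold ratio is below 1; the
motivating design names no test for this comparison, so the hypergeometric
model is this package's interpretive choice.

# The synthetic-data generator

`synthetic_config()` fixes the study conditions; `simulate_study()` builds
the world: i.i.d. genome at a configurable GC fraction, TSSs placed
uniformly with spacing at least twice the assignment window (so peak-gene
links are unambiguous), 50/50 strands, shared peaks drawn at
TSS + Normal(**-205**, 100) bp in transcription direction and duplicated
into both replicates with independent Normal(0, 30) jitter,
replicate-specific extras at further genes, log-normal intensities
(meanlog 3.4, sdlog 0.8 — median ≈ 30 with a few >10× outliers, spanning
roughly an order of magnitude; the intensity model is a stand-in, as no
generating model is prescribed), and motif instances planted in the
promoter window `[TSS-300, TSS-100)`.

Planting is **differential**: bound-gene promoters receive motifs at
`motif_plant_freqs` (defaults E2F 0.35, DREF 0.20, FOXJ2 0.15, RAM 0.25)
and unbound promoters at `motif_background_freqs` (defaults 0.07, 0.05,
0.15, 0.06). This encodes the structure the enrichment stage exists to
detect — binding-associated motifs several-fold more frequent on bound
promoters — while FOXJ2's equal frequencies emulate a generally
distributed promoter element that is *not* binding-specific. Each planted
base is the PWM consensus with probability `motif_plant_strength`
(default 0.9) and a background draw otherwise; strength 1 plants exact
consensus sites whose rescored score equals the PWM maximum (a ledger
invariant under test). Overlapping plants within one promoter are redrawn
up to 20 times, then reported.

Randomness is a single integer seed from which each stage (genome, TSS,
plants, peaks, …) derives an independent substream, so changing one
stage's parameters never perturbs another stage's draws; identical seeds
give byte-identical FASTA/TSV outputs.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: read-level noise and coverage shape
(peaks are emitted directly), chromatin or nucleosome structure,
non-uniform genomic base composition (the background is i.i.d.), motif
positional preference within the promoter beyond the fixed window,
correlated motif co-occurrence beyond independent planting, and real
ortholog topology (the synthetic map has configurable fan-out but no
paralog structure). The bundled PWMs are **synthetic, illustrative
matrices** carrying the field's motif names; no published matrices are
included.

# Problem sizes and numerical conventions

The packaged analyses and checks run at a deliberately desk-sized scale:
a 4 × 4-Mb genome with 3600 genes, 1236 shared + 951/101 unique peaks
(matching the replicate accounting of the motivating design), 200-bp
regions, five scrambles, five background sets of 1000 promoters, and
oracle suites of 500 random matching instances and full `4^w`
enumerations at widths ≤ 8. Coordinates are 0-based half-open everywhere
inside the package; BED output keeps that convention and GFF3 output
converts to 1-based inclusive. Degenerate inputs have defined behaviour:
zero genes give an empty annotation, jitter SD ≤ 0 duplicates summits
exactly, empty motif panels give zero-column presence matrices, all-N
regions are flagged unscorable and excluded from denominators, and empty
assignments error rather than returning an empty histogram.

# Known limitations

* The Šidák sequence-level p-value is conservative for palindromic or
  self-overlapping motifs; an exact clump-corrected (declumped) null is
  not implemented.
* Enrichment ratios are attenuated by the peak-window/promoter-window
  geometry described above; they order motifs correctly but are not
  unbiased estimates of the planted frequency ratio.
* One peak links to at most one gene in generator output by construction
  (gene spacing ≥ 2 × window), so one-to-many assignment is exercised only
  in unit tests, not in the end-to-end workflow.
* The calibration chooses among a fixed candidate grid; it does not
  optimize a continuous threshold.
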