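test_that("genome generation is deterministic and matches the GC model", {
  cfg <- synthetic_config(n_chroms = 2, chrom_length = 2e5, n_genes = 30,
                          n_shared_peaks = 20, n_unique_rep1 = 5,
                          n_unique_rep2 = 5, gc_fraction = 0.5, seed = 42)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$tss, g2$tss)
  expect_equal(unname(Biostrings::width(g1$genome)), c(2e5, 2e5))

  # observed GC within 3 SD of Binomial(L, gc)
  L <- sum(Biostrings::width(g1$genome))
  gc_obs <- sum(Biostrings::letterFrequency(g1$genome, "GC"))
  expect_lt(abs(gc_obs - L * 0.5), 3 * sqrt(L * 0.25))

  # a biased genome shows the bias
  cfg3 <- synthetic_config(n_chroms = 1, chrom_length = 1e5, n_genes = 10,
                           n_shared_peaks = 5, n_unique_rep1 = 0,
                           n_unique_rep2 = 0, gc_fraction = 0.3, seed = 7)
  g3 <- generate_genome(cfg3)
  gc3 <- sum(Biostrings::letterFrequency(g3$genome, "GC"))
  expect_lt(abs(gc3 - 1e5 * 0.3), 3 * sqrt(1e5 * 0.3 * 0.7))
})

test_that("zero genes yields an empty annotation; infeasible configs error", {
  cfg <- synthetic_config(n_genes = 0, n_shared_peaks = 0, n_unique_rep1 = 0,
                          n_unique_rep2 = 0, chrom_length = 5e4, seed = 1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$tss), 0)
  expect_equal(unname(Biostrings::width(g$genome)[1]), 5e4)

  expect_error(synthetic_config(n_genes = 5, n_shared_peaks = 10,
                                n_unique_rep1 = 0, n_unique_rep2 = 0),
               "infeasible")
  cfg_tight <- synthetic_config(n_genes = 500, chrom_length = 1e5,
                                n_chroms = 1, n_shared_peaks = 0,
                                n_unique_rep1 = 0, n_unique_rep2 = 0)
  expect_error(generate_annotation(cfg_tight), "chrom_length|genes")
})

test_that("gene placement respects spacing, margins and strand balance", {
  cfg <- synthetic_config(n_chroms = 2, chrom_length = 2e6, n_genes = 400,
                          seed = 3)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 400)
  for (ch in unique(ann$chrom)) {
    tss <- sort(ann$tss[ann$chrom == ch])
    expect_true(all(diff(tss) >= 2 * cfg$assignment_window))
    expect_true(all(tss >= cfg$assignment_window &
                    tss <= cfg$chrom_length - cfg$assignment_window))
  }
  expect_true(all(ann$strand %in% c("+", "-")))
  # 50/50 strand model: 3-SD binomial band
  expect_lt(abs(sum(ann$strand == "+") - 200), 3 * sqrt(400 * 0.25))
})

test_that("motif planting covers the forced, empty and binomial cases", {
  pwms <- synthetic_motifs()
  base_cfg <- function(freqs, strength, seed = 5, n_genes = 100)
    synthetic_config(n_chroms = 1, chrom_length = (n_genes + 2) * 4000 + 1e4,
                     n_genes = n_genes, n_shared_peaks = 0,
                     n_unique_rep1 = 0, n_unique_rep2 = 0,
                     motif_plant_freqs = freqs,
                     motif_plant_strength = strength, seed = seed)

  # all frequencies zero: genome untouched, ledger empty
  cfg0 <- base_cfg(c(E2F = 0), 1)
  g <- generate_genome(cfg0)
  pl0 <- plant_motifs(g$genome, g$tss, pwms, cfg0)
  expect_identical(as.character(pl0$genome), as.character(g$genome))
  expect_equal(nrow(pl0$ledger), 0)

  # forced case: every promoter gets the exact consensus once
  cfg1 <- base_cfg(c(E2F = 1), 1)
  g1 <- generate_genome(cfg1)
  pl1 <- plant_motifs(g1$genome, g1$tss, pwms, cfg1)
  expect_equal(nrow(pl1$ledger), 100)
  expect_true(all(pl1$ledger$instance == pwm_consensus(pwms$E2F)))
  # and the genome really carries it (strand-aware)
  for (k in seq_len(nrow(pl1$ledger))) {
    row <- pl1$ledger[k, ]
    got <- as.character(Biostrings::subseq(
      pl1$genome[[row$chrom]], row$start + 1, row$start + nchar(row$instance)))
    want <- if (row$strand == "+") row$instance else
      regulonscan:::revcomp(row$instance)
    expect_identical(got, want)
  }
  # rescoring every planted instance attains the PWM maximum score
  max_score <- sum(apply(pwms$E2F$log_odds, 1, max))
  sc <- vapply(pl1$ledger$instance, function(s)
    score_window(pwms$E2F, s), numeric(1))
  expect_equal(unname(sc), rep(max_score, 100))

  # binomial count: freq 0.4 over 500 genes within 3 SD
  cfg2 <- base_cfg(c(E2F = 0.4), 1, seed = 9, n_genes = 500)
  g2 <- generate_genome(cfg2)
  pl2 <- plant_motifs(g2$genome, g2$tss, pwms, cfg2)
  expect_lt(abs(nrow(pl2$ledger) - 200), 3 * sqrt(500 * 0.4 * 0.6))

  # plants land inside the promoter window of their gene
  win <- regulonscan:::promoter_window(g2$tss$tss, g2$tss$strand)
  rownames(win) <- g2$tss$gene_id
  ok <- pl2$ledger$start >= win[pl2$ledger$gene_id, "start"] &
    pl2$ledger$start + nchar(pl2$ledger$instance) <=
      win[pl2$ledger$gene_id, "end"]
  expect_true(all(ok))
})

test_that("peak replicates honour the jitter, offset and sharing model", {
  # degenerate: zero jitter and no extras duplicates summits exactly
  cfg <- synthetic_config(n_chroms = 1, chrom_length = 5e5, n_genes = 100,
                          n_shared_peaks = 80, n_unique_rep1 = 0,
                          n_unique_rep2 = 0, summit_jitter_sd = 0, seed = 2)
  ann <- generate_annotation(cfg)
  pk <- generate_peak_replicates(ann, cfg)
  expect_identical(pk$rep1$summit, pk$rep2$summit)
  expect_identical(pk$rep1$chrom, pk$rep2$chrom)

  # shared peaks are recovered as Class A at the default distance
  cfg2 <- synthetic_config(n_chroms = 2, chrom_length = 2.2e6, n_genes = 1000,
                           n_shared_peaks = 1000, n_unique_rep1 = 0,
                           n_unique_rep2 = 0, summit_jitter_sd = 30, seed = 4)
  ann2 <- generate_annotation(cfg2)
  pk2 <- generate_peak_replicates(ann2, cfg2)
  cl <- classify_replicates(pk2$rep1, pk2$rep2, max_dist = 200)
  # oracle: P(|N(0, sqrt(2)*30)| > 200) ~ 2.4e-6, so >= 99% recovery
  expect_gte(nrow(cl$class_a), 990)

  # mode of the summit-TSS histogram falls in the bin containing -205
  cfg3 <- synthetic_config(n_chroms = 2, chrom_length = 2.2e6, n_genes = 1000,
                           n_shared_peaks = 1000, n_unique_rep1 = 0,
                           n_unique_rep2 = 0, summit_jitter_sd = 0,
                           summit_tss_offset_sd = 40, seed = 6)
  ann3 <- generate_annotation(cfg3)
  pk3 <- generate_peak_replicates(ann3, cfg3)
  asn <- assign_peaks_to_tss(pk3$rep1, ann3, window = 2000)
  dd <- distance_distribution(asn)
  i <- which(dd$bin_centers == dd$mode_bin_center)
  expect_true(dd$bin_edges[i] <= -205 && -205 < dd$bin_edges[i + 1])

  # intensities span the log-normal model: few >10x-median outliers
  s <- intensity_summary(pk2$rep1)
  expect_lt(s$n_over_fold / nrow(pk2$rep1), 0.02)

  # truth table accounts for every peak
  expect_equal(nrow(pk2$truth), 1000)
  expect_setequal(pk2$truth$summit_rep1, pk2$rep1$summit)
})

test_that("generator substreams are independent across stages", {
  mk <- function(jitter) synthetic_config(
    n_chroms = 1, chrom_length = 5e5, n_genes = 60, n_shared_peaks = 40,
    n_unique_rep1 = 5, n_unique_rep2 = 5, summit_jitter_sd = jitter,
    seed = 11)
  g_a <- generate_genome(mk(0))
  g_b <- generate_genome(mk(50))
  # changing the peak stage's parameters leaves genome and annotation alone
  expect_identical(as.character(g_a$genome), as.character(g_b$genome))
  expect_identical(g_a$tss, g_b$tss)
})

test_that("simulate_study plants differentially in bound vs unbound promoters", {
  pwms <- synthetic_motifs()
  cfg <- synthetic_config(
    n_chroms = 2, chrom_length = 1.3e6, n_genes = 600,
    n_shared_peaks = 250, n_unique_rep1 = 30, n_unique_rep2 = 20,
    motif_plant_freqs = c(E2F = 0.4), motif_background_freqs = c(E2F = 0.05),
    motif_plant_strength = 1, seed = 13)
  st <- simulate_study(cfg, pwms)

  bound_genes <- st$truth$gene_id
  expect_length(bound_genes, 300)
  n_bound_plants <- sum(st$ledger$bound)
  n_bg_plants <- sum(!st$ledger$bound)
  # binomial 3-SD bands around 0.4 * 300 and 0.05 * 300
  expect_lt(abs(n_bound_plants - 0.4 * 300), 3 * sqrt(300 * 0.4 * 0.6))
  expect_lt(abs(n_bg_plants - 0.05 * 300), 3 * sqrt(300 * 0.05 * 0.95))
  expect_true(all(st$ledger$gene_id[st$ledger$bound] %in% bound_genes))
  expect_false(any(st$ledger$gene_id[!st$ledger$bound] %in% bound_genes))

  # every plant is present in the emitted genome
  for (k in sample(nrow(st$ledger), 20)) {
    row <- st$ledger[k, ]
    got <- as.character(Biostrings::subseq(
      st$genome[[row$chrom]], row$start + 1, row$start + nchar(row$instance)))
    want <- if (row$strand == "+") row$instance else
      regulonscan:::revcomp(row$instance)
    expect_identical(got, want)
  }

  # deterministic given the seed
  st2 <- simulate_study(cfg, pwms)
  expect_identical(as.character(st$genome), as.character(st2$genome))
  expect_identical(st$ledger, st2$ledger)
  expect_identical(st$rep1$summit, st2$rep1$summit)
})
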