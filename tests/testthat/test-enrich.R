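mk_presence <- function(rows, motifs) {
  m <- matrix(FALSE, nrow = length(rows), ncol = length(motifs),
              dimnames = list(names(rows), motifs))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- TRUE
  structure(m, scorable = rep(TRUE, length(rows)),
            class = c("motif_presence", "matrix"))
}

test_that("constellation counts partition the regions", {
  motifs <- c("E2F", "DREF", "FOXJ2", "RAM")
  rows <- list(r1 = "E2F", r2 = "E2F", r3 = c("E2F", "RAM"), r4 = character(0))
  cc <- constellation_counts(mk_presence(rows, motifs))
  expect_equal(unname(cc$by_size[c("0", "1", "2")]), c(1, 2, 1))
  expect_equal(cc$counts[["E2F"]], 2)
  expect_equal(cc$counts[["E2F+RAM"]], 1)
  expect_equal(cc$counts[["none"]], 1)
  expect_equal(sum(cc$counts), cc$n_regions)

  # all-false matrix: everything in "none"
  cc0 <- constellation_counts(mk_presence(list(a = character(0),
                                               b = character(0)), motifs))
  expect_equal(cc0$counts[["none"]], 2)

  # random matrices: the counts always sum to the number of regions
  set.seed(61)
  for (k in 1:25) {
    n <- sample(1:40, 1)
    rows <- lapply(seq_len(n), function(i)
      motifs[runif(4) < 0.4])
    names(rows) <- sprintf("r%03d", seq_len(n))
    cc_r <- constellation_counts(mk_presence(rows, motifs))
    expect_equal(sum(cc_r$counts), n)
    expect_equal(sum(cc_r$by_size), n)
    expect_equal(sum(cc_r$percent_by_size), 100)
  }
})

test_that("promoter windows are strand-aware and edge-safe", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(rand_dna(1, 2000))))
  ann <- data.frame(gene_id = c("gp", "gm", "edge"), chrom = "chr1",
                    tss = c(1000, 1000, 100), strand = c("+", "-", "+"))
  expect_warning(win <- extract_promoter_windows(genome, ann), "dropped")
  expect_equal(names(win), c("gp", "gm"))
  expect_equal(unname(Biostrings::width(win)), c(200, 200))
  # plus strand: [700, 900); minus strand: mirror, reverse-complemented
  expect_equal(as.character(win[["gp"]]),
               as.character(Biostrings::subseq(genome[[1]], 701, 900)))
  expect_equal(as.character(win[["gm"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[[1]], 1101, 1300))))
})

test_that("enrichment against the bound regions themselves is exactly null", {
  pwms <- synthetic_motifs()["E2F"]
  set.seed(62)
  bound <- rand_dna(150, 200)
  cons <- pwm_consensus(pwms$E2F)
  for (i in 1:50) substr(bound[i], 20, 27) <- cons
  # background pool == bound set and set_size == pool size: every background
  # set is the whole pool, so the ratio is exactly 1 with zero spread
  er <- background_promoter_enrichment(
    pwms, bound, bound, thresholds = c(E2F = 1e-2),
    n_sets = 5, set_size = 150, seed = 9)
  expect_equal(er$table$ratio, 1)
  expect_equal(unname(er$table$background_sd), 0)
  expect_equal(dim(er$background_fracs), c(5, 1))
  expect_gt(er$table$frac_bound, 0.3)  # the planted third is being detected
})

test_that("a motif planted only in bound promoters is detected as enriched", {
  pwms <- synthetic_motifs()["E2F"]
  set.seed(63)
  bound <- rand_dna(200, 200)
  cons <- pwm_consensus(pwms$E2F)
  planted <- runif(200) < 0.4
  for (i in which(planted)) {
    off <- sample(193, 1)
    substr(bound[i], off, off + 7) <- cons
  }
  pool <- rand_dna(600, 200)
  expect_warning(
    er <- background_promoter_enrichment(pwms, bound, pool,
                                         thresholds = c(E2F = 1e-2),
                                         n_sets = 5, set_size = 1000,
                                         seed = 10),
    "replacement")
  tab <- er$table
  se_bound <- sqrt(tab$frac_bound * (1 - tab$frac_bound) / 200)
  expect_gt(tab$frac_bound - 3 * se_bound,
            tab$background_mean + 3 * tab$background_sd)
  expect_gt(tab$ratio, 1)

  expect_error(background_promoter_enrichment(pwms, bound, character(0),
                                              thresholds = c(E2F = 1e-2)),
               "empty")
})

test_that("category fractions use ANY-peak semantics and a none column", {
  motifs <- c("E2F", "RAM")
  presence <- mk_presence(list(p1 = "E2F", p2 = character(0), p3 = "RAM"),
                          motifs)
  asn <- fake_assignment(c(-100, -200, -300))
  asn$links$peak_id <- c("p1", "p2", "p3")
  asn$links$gene_id <- c("g1", "g2", "g2")

  cats <- data.frame(gene_id = c("g1", "g2", "g2", "g_missing"),
                     category = c("catA", "catA", "catB", "catC"))
  tab <- category_motif_fractions(asn, presence, cats)

  # g1 has {E2F}; g2 has peaks p2 (none) and p3 (RAM) -> RAM via ANY
  expect_equal(tab$fractions["catA", "E2F"], 0.5)
  expect_equal(tab$fractions["catA", "RAM"], 0.5)
  expect_equal(tab$fractions["catA", "none"], 0)
  expect_equal(tab$fractions["catB", "RAM"], 1)
  # category with no assigned genes: explicit NA row
  expect_true(all(is.na(tab$fractions["catC", ])))
  expect_equal(unname(tab$gene_counts["catC"]), 0L)
  # the "all" row covers every assigned gene
  expect_equal(unname(tab$gene_counts["all"]), 2L)

  # single gene, single peak with {E2F}: fraction 1, none 0
  tab1 <- category_motif_fractions(
    structure(list(links = data.frame(peak_id = "p1", gene_id = "g1",
                                      distance = 0),
                   window = 2000), class = "peak_gene_assignment"),
    mk_presence(list(p1 = "E2F"), motifs),
    data.frame(gene_id = "g1", category = "solo"))
  expect_equal(tab1$fractions["solo", "E2F"], 1)
  expect_equal(tab1$fractions["solo", "none"], 0)
})

test_that("none-fraction agrees with a gene-level constellation recount", {
  set.seed(64)
  motifs <- c("E2F", "DREF", "FOXJ2", "RAM")
  n_peaks <- 60
  rows <- lapply(seq_len(n_peaks), function(i) motifs[runif(4) < 0.3])
  names(rows) <- sprintf("p%02d", seq_len(n_peaks))
  presence <- mk_presence(rows, motifs)
  genes <- sprintf("g%02d", sample(1:25, n_peaks, replace = TRUE))
  asn <- structure(list(links = data.frame(peak_id = names(rows),
                                           gene_id = genes, distance = 0),
                        window = 2000), class = "peak_gene_assignment")
  cats <- data.frame(gene_id = unique(genes), category = "everything")
  tab <- category_motif_fractions(asn, presence, cats)

  # oracle recount: a gene is empty iff none of its peaks has any motif
  gene_empty <- tapply(rowSums(presence[names(rows), ]) == 0, genes, all)
  expect_equal(tab$fractions["everything", "none"],
               mean(gene_empty[unique(genes)]))
})
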