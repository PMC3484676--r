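#' Motif constellation counts
#'
#' Partitions regions by the exact subset of panel motifs present (their
#' "constellation"): each scorable region contributes to exactly one subset
#' key, so the counts sum to the number of scorable regions. Also reports the
#' distribution over constellation sizes (0 = none of the panel motifs, up to
#' the full panel).
#'
#' @param presence A [scan_regions()] presence matrix.
#' @return An object of class `constellation_counts`: list with `counts`
#'   (named integer vector; keys are `+`-joined motif subsets, `"none"` for
#'   the empty set), `by_size` (counts indexed by subset size 0..K),
#'   `percent_by_size`, and `n_regions` (scorable regions).
#' @export
constellation_counts <- function(presence) {
  if (length(presence) == 0L || ncol(presence) == 0L) {
    n <- nrow(presence) %||% 0L
    out <- list(counts = stats::setNames(as.integer(n), "none")[n > 0],
                by_size = stats::setNames(as.integer(n), "0"),
                percent_by_size = stats::setNames(100 * (n > 0), "0"),
                n_regions = n)
    class(out) <- "constellation_counts"
    return(out)
  }
  ok <- stats::complete.cases(presence)
  m <- presence[ok, , drop = FALSE]
  motifs <- colnames(m)
  key <- apply(m, 1, function(r) {
    s <- motifs[r]
    if (length(s) == 0L) "none" else paste(s, collapse = "+")
  })
  counts <- sort(table(key), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  sizes <- rowSums(m)
  by_size <- tabulate(sizes + 1L, nbins = ncol(m) + 1L)
  names(by_size) <- as.character(0:ncol(m))
  out <- list(counts = counts, by_size = by_size,
              percent_by_size = 100 * by_size / max(1L, nrow(m)),
              n_regions = nrow(m))
  class(out) <- "constellation_counts"
  out
}

#' @export
print.constellation_counts <- function(x, ...) {
  cat(sprintf("constellations over %d regions:\n", x$n_regions))
  for (s in names(x$by_size))
    cat(sprintf("  %s motif(s): %d (%.1f%%)\n", s, x$by_size[[s]],
                x$percent_by_size[[s]]))
  invisible(x)
}

#' Extract strand-aware promoter windows
#'
#' Returns the `[TSS-300, TSS-100)` window (in transcription direction,
#' mirrored about the TSS on the minus strand and reverse-complemented to
#' promoter sense) for every gene. Genes whose window runs off a chromosome
#' end are dropped with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window_rel Length-2 window relative to the TSS (default
#'   `c(-300, -100)`).
#' @return A [Biostrings::DNAStringSet] named by `gene_id`.
#' @export
extract_promoter_windows <- function(genome, annotation,
                                     window_rel = c(-300, -100)) {
  win <- promoter_window(annotation$tss, annotation$strand, window_rel)
  lens <- Biostrings::width(genome)[match(annotation$chrom, names(genome))]
  ok <- !is.na(lens) & win[, 1] >= 0 & win[, 2] <= lens
  if (any(!ok))
    warning(sum(!ok), " gene(s) dropped: promoter window outside chromosome")
  annotation <- annotation[ok, , drop = FALSE]
  win <- win[ok, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(rep("", nrow(annotation)))
  for (ch in unique(annotation$chrom)) {
    idx <- which(annotation$chrom == ch)
    at <- IRanges::IRanges(start = win[idx, 1] + 1L, end = win[idx, 2])
    seqs[idx] <- Biostrings::extractAt(genome[[ch]], at)
  }
  minus <- annotation$strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- annotation$gene_id
  seqs
}

#' Motif enrichment of bound regions against unbound-promoter backgrounds
#'
#' Computes, per motif, the fraction of bound regions carrying the motif and
#' compares it with the mean fraction over `n_sets` random samples of
#' `set_size` unbound promoters (the 5 x 1000 unbound-promoter background
#' design). The enrichment ratio is `frac_bound / background_mean`; an
#' empirical z-score against the background sets is included for convenience.
#' No multiple-testing correction is applied: ratios, not p-values, are the
#' primary output.
#'
#' @param pwms Named list of [build_pwm()] objects.
#' @param bound_regions Sequences of the bound regions (e.g. 200-bp peak
#'   windows from [extract_peak_sequences()]).
#' @param unbound_promoters Pool of unbound-promoter sequences (e.g. from
#'   [extract_promoter_windows()] on genes without peaks). If the pool is
#'   smaller than `set_size`, sampling falls back to with-replacement with a
#'   warning.
#' @param thresholds Per-motif p-value thresholds as in [scan_regions()].
#' @param n_sets Number of background sets (default 5).
#' @param set_size Promoters per background set (default 1000).
#' @param seed Optional integer seed for the background sampling.
#' @return An object of class `enrichment_result`: list with `table` (per
#'   motif: frac_bound, background_mean, background_sd, ratio, z) and
#'   `background_fracs` (n_sets x motifs matrix).
#' @export
background_promoter_enrichment <- function(pwms, bound_regions,
                                           unbound_promoters, thresholds,
                                           n_sets = 5, set_size = 1000,
                                           seed = NULL) {
  bound_regions <- as_sequences(bound_regions)
  unbound_promoters <- as_sequences(unbound_promoters)
  if (length(unbound_promoters) == 0L)
    stop("the unbound-promoter pool is empty")
  replace <- length(unbound_promoters) < set_size
  if (replace)
    warning("unbound pool (", length(unbound_promoters),
            ") smaller than set_size (", set_size,
            "); sampling with replacement")
  ids <- names(pwms)
  dists <- lapply(pwms, score_distribution)

  pm_bound <- scan_regions(pwms, bound_regions, thresholds, dists = dists)
  frac <- function(pm) colMeans(pm, na.rm = TRUE)
  frac_bound <- frac(pm_bound)

  sets <- with_seed(seed %||% stage_seed(1L, "background"), {
    lapply(seq_len(n_sets), function(k)
      unbound_promoters[sample.int(length(unbound_promoters), set_size,
                                   replace = replace)])
  })
  bg <- vapply(sets, function(s)
    frac(scan_regions(pwms, s, thresholds, dists = dists)),
    numeric(length(ids)))
  bg <- t(matrix(bg, nrow = length(ids), dimnames = list(ids, NULL)))
  bg_mean <- colMeans(bg)
  bg_sd <- apply(bg, 2, stats::sd)
  tab <- data.frame(motif_id = ids, frac_bound = frac_bound,
                    background_mean = bg_mean, background_sd = bg_sd,
                    ratio = frac_bound / bg_mean,
                    z = (frac_bound - bg_mean) / bg_sd,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, background_fracs = bg, n_sets = n_sets,
                 set_size = set_size),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("motif enrichment vs %d background sets of %d promoters:\n",
              x$n_sets, x$set_size))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-category motif fractions (heat-map table)
#'
#' For every gene category, the fraction of its peak-assigned genes whose
#' peaks contain each motif at least once (a gene is motif-positive if ANY
#' peak assigned to it carries the motif), plus a `none` column (genes whose
#' peaks carry none of the panel motifs) and an `all` row over every assigned
#' gene. Categories with no assigned genes get an explicit `NA` row.
#'
#' @param assignment A [assign_peaks_to_tss()] result.
#' @param presence A [scan_regions()] presence matrix whose rows are the peak
#'   ids appearing in the assignment links.
#' @param categories data.frame with columns `gene_id` and `category`
#'   (multi-membership allowed).
#' @return An object of class `category_motif_table`: list with `fractions`
#'   (categories x (motifs + none) matrix), `gene_counts` and `motif_ids`.
#' @export
category_motif_fractions <- function(assignment, presence, categories) {
  links <- assignment$links
  motifs <- colnames(presence)
  rows <- rownames(presence)
  known <- links[links$peak_id %in% rows, , drop = FALSE]
  # gene x motif: any assigned peak carries the motif
  genes <- unique(known$gene_id)
  gene_mat <- matrix(FALSE, nrow = length(genes), ncol = length(motifs),
                     dimnames = list(genes, motifs))
  pm <- presence[known$peak_id, , drop = FALSE]
  pm[is.na(pm)] <- FALSE                      # unscorable peaks carry nothing
  for (m in motifs)
    gene_mat[, m] <- as.logical(
      tapply(pm[, m], known$gene_id, any)[genes])
  cats <- c(list(all = genes),
            split(categories$gene_id, categories$category))
  frac <- matrix(NA_real_, nrow = length(cats), ncol = length(motifs) + 1L,
                 dimnames = list(names(cats), c(motifs, "none")))
  gene_counts <- stats::setNames(integer(length(cats)), names(cats))
  for (i in seq_along(cats)) {
    g <- intersect(unique(cats[[i]]), genes)
    gene_counts[i] <- length(g)
    if (length(g) == 0L) next
    sub <- gene_mat[g, , drop = FALSE]
    frac[i, motifs] <- colMeans(sub)
    frac[i, "none"] <- mean(rowSums(sub) == 0L)
  }
  structure(list(fractions = frac, gene_counts = gene_counts,
                 motif_ids = motifs),
            class = "category_motif_table")
}

#' @export
print.category_motif_table <- function(x, ...) {
  cat("per-category motif fractions (genes with >= 1 occurrence):\n")
  print(round(cbind(x$fractions, n_genes = x$gene_counts), 3))
  invisible(x)
}
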