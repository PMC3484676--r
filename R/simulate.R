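#' Generate a synthetic genome and TSS annotation
#'
#' Draws i.i.d. bases at the configured GC fraction and places `n_genes`
#' transcription start sites uniformly at random, subject to a minimum
#' inter-gene spacing of twice the assignment window (so downstream
#' peak-to-gene links are unambiguous) and a margin that keeps promoter
#' windows and peak flanks inside the chromosome. Strands are assigned 50/50.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `tss`, a data.frame with columns `gene_id`, `chrom`, `tss` (0-based bp)
#'   and `strand`.
#' @export
generate_genome <- function(config) {
  validate_config(config)
  gc <- config$gc_fraction
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  L <- config$chrom_length
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))

  genome <- with_seed(stage_seed(config$seed, "genome"), {
    seqs <- vapply(chrom_names, function(ch)
      paste0(sample(DNA_BASES4, L, replace = TRUE, prob = base_probs),
             collapse = ""), character(1))
    Biostrings::DNAStringSet(seqs)
  })
  names(genome) <- chrom_names
  list(genome = genome, tss = generate_annotation(config))
}

#' Generate only the TSS annotation of a synthetic study
#'
#' The annotation half of [generate_genome()], for workflows (e.g. replicate
#' peak simulation) that never touch sequence. Uses the same substream, so
#' the annotation is identical to the one `generate_genome` returns for the
#' same config.
#'
#' @inheritParams generate_genome
#' @return TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
generate_annotation <- function(config) {
  validate_config(config)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  with_seed(stage_seed(config$seed, "tss"), place_genes(config, chrom_names))
}

# Uniform placement with guaranteed minimum spacing: draw sorted uniforms on
# the slack interval, then add back the cumulative spacing.
place_genes <- function(config, chrom_names) {
  n <- config$n_genes
  if (n == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tss = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  margin <- config$assignment_window        # keeps promoters/flanks interior
  spacing <- 2 * config$assignment_window
  per_chrom <- tabulate(rep(seq_along(chrom_names), length.out = n),
                        nbins = length(chrom_names))
  out <- vector("list", length(chrom_names))
  for (i in seq_along(chrom_names)) {
    g <- per_chrom[i]
    if (g == 0L) next
    slack <- config$chrom_length - 2 * margin - (g - 1) * spacing
    if (slack <= 0)
      stop(sprintf(paste0(
        "infeasible config: %d genes on %s need %g bp ",
        "(spacing %g, margin %g) but chrom_length is %g"),
        g, chrom_names[i], 2 * margin + (g - 1) * spacing + 1,
        spacing, margin, config$chrom_length), call. = FALSE)
    pos <- floor(margin + sort(stats::runif(g, 0, slack)) +
                   (seq_len(g) - 1) * spacing)
    out[[i]] <- data.frame(chrom = chrom_names[i], tss = pos,
                           stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  ann$gene_id <- sprintf("gene%05d", seq_len(nrow(ann)))
  ann[, c("gene_id", "chrom", "tss", "strand")]
}

# Absolute, 0-based half-open promoter window for one gene: [TSS-300,
# TSS-100) in transcription direction, mirrored about the TSS on the minus
# strand.
promoter_window <- function(tss, strand, rel = c(-300, -100)) {
  width <- rel[2] - rel[1]
  start <- ifelse(strand == "+", tss + rel[1], tss - rel[2])
  cbind(start = start, end = start + width)
}

#' Plant motif instances into promoter windows
#'
#' For each gene and each motif, with probability `motif_plant_freqs[motif]`
#' one instance is written at a uniform-random offset and strand within the
#' gene's promoter window (`[TSS-300, TSS-100)` in transcription direction).
#' Each planted base is the PWM consensus base with probability
#' `motif_plant_strength`, otherwise a background draw. Overlapping plants
#' within one gene are re-drawn up to 20 times, then reported in `failed`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation TSS data.frame as from [generate_genome()].
#' @param pwms Named list of [build_pwm()] objects; names must cover
#'   `names(config$motif_plant_freqs)`.
#' @param config A [synthetic_config()].
#' @param window_rel Length-2 vector, promoter window relative to the TSS.
#' @param freqs Named per-motif plant probabilities; defaults to
#'   `config$motif_plant_freqs`. [simulate_study()] passes
#'   `config$motif_background_freqs` here for unbound genes.
#' @param seed Integer seed for this planting pass; defaults to the config's
#'   planting substream.
#' @return A list with the modified `genome`, a `ledger` data.frame
#'   (`gene_id`, `motif_id`, `chrom`, `start` 0-based, `strand`, `instance`
#'   in motif sense), and a `failed` data.frame of plants that could not be
#'   placed without overlap.
#' @export
plant_motifs <- function(genome, annotation, pwms, config,
                         window_rel = c(-300, -100),
                         freqs = config$motif_plant_freqs,
                         seed = stage_seed(config$seed, "plants")) {
  validate_config(config)
  empty <- data.frame(gene_id = character(0), motif_id = character(0),
                      chrom = character(0), start = numeric(0),
                      strand = character(0), instance = character(0),
                      stringsAsFactors = FALSE)
  if (length(freqs) == 0L || nrow(annotation) == 0L)
    return(list(genome = genome, ledger = empty, failed = empty[0, 1:2]))
  missing_pwm <- setdiff(names(freqs), names(pwms))
  if (length(missing_pwm))
    stop("no PWM supplied for motif(s): ", paste(missing_pwm, collapse = ", "))

  gc <- config$gc_fraction
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  win <- promoter_window(annotation$tss, annotation$strand, window_rel)
  win_len <- window_rel[2] - window_rel[1]
  strength <- config$motif_plant_strength

  ledger <- list(); failed <- list()
  with_seed(seed, {
    for (g in seq_len(nrow(annotation))) {
      placed <- NULL  # occupied [start, end) intervals within this window
      for (m in names(freqs)) {
        if (stats::runif(1) >= freqs[[m]]) next
        pwm <- pwms[[m]]
        w <- pwm$width
        if (w > win_len) {
          failed[[length(failed) + 1L]] <-
            data.frame(gene_id = annotation$gene_id[g], motif_id = m)
          next
        }
        ok <- FALSE
        for (attempt in seq_len(20L)) {
          off <- sample.int(win_len - w + 1L, 1L) - 1L
          if (is.null(placed) ||
              all(off + w <= placed[, 1] | off >= placed[, 2])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          failed[[length(failed) + 1L]] <-
            data.frame(gene_id = annotation$gene_id[g], motif_id = m)
          next
        }
        placed <- rbind(placed, c(off, off + w))
        use_cons <- stats::runif(w) < strength
        bases <- ifelse(use_cons, pwm_consensus_bases(pwm),
                        sample(DNA_BASES4, w, replace = TRUE,
                               prob = base_probs))
        instance <- paste0(bases, collapse = "")
        strand <- sample(c("+", "-"), 1L)
        ledger[[length(ledger) + 1L]] <- data.frame(
          gene_id = annotation$gene_id[g], motif_id = m,
          chrom = annotation$chrom[g], start = win[g, 1] + off,
          strand = strand, instance = instance, stringsAsFactors = FALSE)
      }
    }
  })
  ledger <- if (length(ledger)) do.call(rbind, ledger) else empty
  failed <- if (length(failed)) do.call(rbind, failed) else empty[0, 1:2]

  if (nrow(ledger)) {
    written <- ifelse(ledger$strand == "+", ledger$instance,
                      revcomp(ledger$instance))
    for (ch in unique(ledger$chrom)) {
      idx <- which(ledger$chrom == ch)
      at <- IRanges::IRanges(start = ledger$start[idx] + 1L,
                             width = nchar(written[idx]))
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], at, Biostrings::DNAStringSet(written[idx]))
    }
  }
  list(genome = genome, ledger = ledger, failed = failed)
}

#' Generate two replicate peak sets anchored at synthetic TSSs
#'
#' `n_shared_peaks` base summits are drawn at TSS + Normal(offset_mean,
#' offset_sd) in transcription direction and duplicated into both replicates
#' with independent Normal(0, jitter_sd) jitter (jitter_sd <= 0 duplicates
#' exactly); replicate-specific extras are placed at further distinct genes.
#' Intensities are log-normal; `start`/`end` are summit +/- 100 bp.
#'
#' @inheritParams plant_motifs
#' @return A list of two [peak_set()] data.frames `rep1` and `rep2`, plus
#'   `truth`: the gene each peak was anchored at and its origin class
#'   (`shared`, `rep1_only`, `rep2_only`).
#' @export
generate_peak_replicates <- function(annotation, config) {
  validate_config(config)
  n_sh <- config$n_shared_peaks
  n_u1 <- config$n_unique_rep1
  n_u2 <- config$n_unique_rep2
  need <- n_sh + n_u1 + n_u2
  if (need > nrow(annotation))
    stop(sprintf("config asks for %d peaks but annotation has %d genes",
                 need, nrow(annotation)))
  jit_sd <- max(0, config$summit_jitter_sd)

  res <- with_seed(stage_seed(config$seed, "peaks"), {
    genes <- annotation[sample.int(nrow(annotation), need), , drop = FALSE]
    draw_offset <- function(n)
      round(stats::rnorm(n, config$summit_tss_offset_mean,
                         config$summit_tss_offset_sd))
    signed <- function(off, strand) ifelse(strand == "+", off, -off)
    jitter <- function(n) if (jit_sd > 0) round(stats::rnorm(n, 0, jit_sd))
                          else rep(0, n)
    intensity <- function(n)
      round(stats::rlnorm(n, config$intensity_log_mean,
                          config$intensity_log_sd), 4)

    sh <- genes[seq_len(n_sh), , drop = FALSE]
    base <- sh$tss + signed(draw_offset(n_sh), sh$strand)
    s1 <- base + jitter(n_sh)
    s2 <- base + jitter(n_sh)
    u1 <- genes[n_sh + seq_len(n_u1), , drop = FALSE]
    su1 <- u1$tss + signed(draw_offset(n_u1), u1$strand)
    u2 <- genes[n_sh + n_u1 + seq_len(n_u2), , drop = FALSE]
    su2 <- u2$tss + signed(draw_offset(n_u2), u2$strand)

    clamp <- function(s) pmin(pmax(s, 101), config$chrom_length - 101)
    rep1 <- data.frame(chrom = c(sh$chrom, u1$chrom),
                       summit = clamp(c(s1, su1)),
                       intensity = intensity(n_sh + n_u1),
                       stringsAsFactors = FALSE)
    rep2 <- data.frame(chrom = c(sh$chrom, u2$chrom),
                       summit = clamp(c(s2, su2)),
                       intensity = intensity(n_sh + n_u2),
                       stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = genes$gene_id,
      chrom = genes$chrom,
      origin = rep(c("shared", "rep1_only", "rep2_only"),
                   times = c(n_sh, n_u1, n_u2)),
      summit_rep1 = c(clamp(s1), clamp(su1), rep(NA, n_u2)),
      summit_rep2 = c(clamp(s2), rep(NA, n_u1), clamp(su2)),
      stringsAsFactors = FALSE)
    list(rep1 = rep1, rep2 = rep2, truth = truth)
  })
  finish <- function(df, id) {
    df$start <- df$summit - 100
    df$end <- df$summit + 100
    peak_set(df[, c("chrom", "start", "end", "summit", "intensity")],
             replicate_id = id)
  }
  list(rep1 = finish(res$rep1, "rep1"), rep2 = finish(res$rep2, "rep2"),
       truth = res$truth)
}

#' Simulate a complete synthetic binding study
#'
#' Orchestrates the full generator: genome and TSS annotation, two replicate
#' peak sets anchored at a random subset of genes, and motif planting in
#' every promoter — at `motif_plant_freqs` for genes that carry a peak
#' ("bound" genes) and at `motif_background_freqs` for the rest. This encodes
#' the structure the downstream enrichment analysis is designed to detect:
#' binding-associated motifs are several-fold more frequent on bound
#' promoters, while a generally distributed motif can be given equal
#' frequencies on both sides.
#'
#' @param config A [synthetic_config()].
#' @param pwms Named list of [build_pwm()] objects covering the motifs named
#'   in the config's frequency vectors.
#' @return A list with `genome` (motifs planted), `tss`, `rep1`, `rep2`,
#'   `truth` (peak-to-gene ground truth from [generate_peak_replicates()]),
#'   `ledger` (all plants, with a `bound` flag), and `failed`.
#' @export
simulate_study <- function(config, pwms) {
  validate_config(config)
  gen <- generate_genome(config)
  pk <- generate_peak_replicates(gen$tss, config)
  bound <- gen$tss$gene_id %in% pk$truth$gene_id

  pl_bound <- plant_motifs(gen$genome, gen$tss[bound, , drop = FALSE], pwms,
                           config, freqs = config$motif_plant_freqs,
                           seed = stage_seed(config$seed, "plants"))
  pl_bg <- plant_motifs(pl_bound$genome, gen$tss[!bound, , drop = FALSE],
                        pwms, config,
                        freqs = config$motif_background_freqs,
                        seed = stage_seed(config$seed, "background"))
  add_flag <- function(df, flag) {
    if (nrow(df)) df$bound <- flag
    df
  }
  ledger <- rbind(add_flag(pl_bound$ledger, TRUE),
                  add_flag(pl_bg$ledger, FALSE))
  list(genome = pl_bg$genome, tss = gen$tss, rep1 = pk$rep1, rep2 = pk$rep2,
       truth = pk$truth, ledger = ledger,
       failed = rbind(pl_bound$failed, pl_bg$failed))
}
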