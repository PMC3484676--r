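#' Configuration for the synthetic ChIP-seq study generator
#'
#' Bundles every tunable of the synthetic-data module: genome shape, gene
#' placement, replicate peak structure, summit placement relative to the TSS,
#' motif planting, and peak intensities. The defaults describe the study
#' conditions the pipeline is designed around: two biological replicates with
#' a concordant core and replicate-specific extras, summits centred 205 bp
#' upstream of the TSS, and intensities spanning roughly an order of
#' magnitude.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes (TSS records) across chromosomes.
#' @param gc_fraction Genome GC content, in `[0, 1]`.
#' @param n_shared_peaks Number of peaks shared by both replicates.
#' @param n_unique_rep1,n_unique_rep2 Replicate-specific extra peaks.
#' @param summit_jitter_sd SD (bp) of the independent per-replicate jitter
#'   applied to shared summits; values `<= 0` mean exact duplication.
#' @param summit_tss_offset_mean,summit_tss_offset_sd Normal model (bp) of the
#'   summit position relative to the TSS; negative mean = upstream.
#' @param motif_plant_freqs Named numeric vector, per-motif probability that a
#'   bound gene's promoter receives one planted instance.
#' @param motif_background_freqs Named numeric vector, the same probability
#'   for promoters of genes without a peak. The defaults encode the study
#'   structure the pipeline is meant to detect: the E2F-family, replication
#'   element and novel motifs are several-fold rarer on unbound promoters,
#'   while the Forkhead-family motif occurs at the same rate everywhere (a
#'   generally distributed promoter element, not a binding-specific one).
#' @param motif_plant_strength Probability, per planted base, of drawing the
#'   PWM consensus base rather than a background base; 1 plants the exact
#'   consensus.
#' @param intensity_log_mean,intensity_log_sd Log-normal intensity model
#'   (natural-log scale).
#' @param assignment_window Peak-to-TSS assignment window (bp); genes are
#'   placed at least twice this far apart so peak-gene links are unambiguous.
#' @param seed Integer master seed; every stage derives its own substream.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_genes = 50, n_shared_peaks = 30,
#'                         n_unique_rep1 = 5, n_unique_rep2 = 5, seed = 1)
#' @export
synthetic_config <- function(n_chroms = 2L,
                             chrom_length = 1e6,
                             n_genes = 400L,
                             gc_fraction = 0.5,
                             n_shared_peaks = 300L,
                             n_unique_rep1 = 60L,
                             n_unique_rep2 = 20L,
                             summit_jitter_sd = 30,
                             summit_tss_offset_mean = -205,
                             summit_tss_offset_sd = 100,
                             motif_plant_freqs = c(E2F = 0.35, DREF = 0.20,
                                                   FOXJ2 = 0.15, RAM = 0.25),
                             motif_background_freqs = c(E2F = 0.07,
                                                        DREF = 0.05,
                                                        FOXJ2 = 0.15,
                                                        RAM = 0.06),
                             motif_plant_strength = 0.9,
                             intensity_log_mean = 3.4,
                             intensity_log_sd = 0.8,
                             assignment_window = 2000,
                             seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes), gc_fraction = gc_fraction,
    n_shared_peaks = as.integer(n_shared_peaks),
    n_unique_rep1 = as.integer(n_unique_rep1),
    n_unique_rep2 = as.integer(n_unique_rep2),
    summit_jitter_sd = summit_jitter_sd,
    summit_tss_offset_mean = summit_tss_offset_mean,
    summit_tss_offset_sd = summit_tss_offset_sd,
    motif_plant_freqs = motif_plant_freqs,
    motif_background_freqs = motif_background_freqs,
    motif_plant_strength = motif_plant_strength,
    intensity_log_mean = intensity_log_mean,
    intensity_log_sd = intensity_log_sd,
    assignment_window = as.numeric(assignment_window),
    seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_config <- function(cfg) {
  for (f in c("n_chroms", "n_genes", "n_shared_peaks",
              "n_unique_rep1", "n_unique_rep2"))
    if (cfg[[f]] < 0L) stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  stopifnot_scalar_number(cfg$gc_fraction, "gc_fraction", 0, 1)
  stopifnot_scalar_number(cfg$motif_plant_strength, "motif_plant_strength",
                          0, 1)
  for (f in c("motif_plant_freqs", "motif_background_freqs")) {
    if (length(cfg[[f]]) > 0) {
      if (is.null(names(cfg[[f]])) || any(names(cfg[[f]]) == ""))
        stop(sprintf("`%s` must be named by motif id", f), call. = FALSE)
      if (any(cfg[[f]] < 0 | cfg[[f]] > 1))
        stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (cfg$assignment_window <= 0)
    stop("`assignment_window` must be > 0", call. = FALSE)
  if (cfg$chrom_length <= 2 * cfg$assignment_window)
    stop(sprintf(
      "`chrom_length` (%g) must exceed 2 x assignment_window (%g)",
      cfg$chrom_length, 2 * cfg$assignment_window), call. = FALSE)
  n_peaks <- cfg$n_shared_peaks + cfg$n_unique_rep1 + cfg$n_unique_rep2
  if (n_peaks > cfg$n_genes)
    stop(sprintf(paste0(
      "infeasible config: %d peaks requested (shared + unique) but only %d ",
      "genes available to anchor them"), n_peaks, cfg$n_genes), call. = FALSE)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      sprintf("%d chrom(s) x %g bp, %d genes, GC %.2f",
              x$n_chroms, x$chrom_length, x$n_genes, x$gc_fraction), "\n")
  cat(sprintf("  peaks: %d shared + %d/%d unique; jitter sd %g bp; offset N(%g, %g)\n",
              x$n_shared_peaks, x$n_unique_rep1, x$n_unique_rep2,
              x$summit_jitter_sd, x$summit_tss_offset_mean,
              x$summit_tss_offset_sd))
  if (length(x$motif_plant_freqs))
    cat("  plant freqs:", paste(sprintf("%s=%.2f", names(x$motif_plant_freqs),
                                        x$motif_plant_freqs), collapse = ", "),
        sprintf("(strength %.2f)\n", x$motif_plant_strength))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
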