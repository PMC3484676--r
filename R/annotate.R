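#' Assign peaks to transcription start sites
#'
#' Links every peak to every gene on the same chromosome whose TSS lies
#' within `window` bp of the peak summit (inclusive). Distances are signed
#' and strand-aware: negative means the summit lies upstream of the TSS in
#' the gene's transcription direction. A peak may link to several genes and
#' a gene to several peaks.
#'
#' @param peaks A [peak_set()] or the `class_a` table of a
#'   [classify_replicates()] result.
#' @param annotation TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`),
#'   e.g. from [generate_genome()] or [read_tss()].
#' @param window Assignment window in bp (default 2000, inclusive).
#' @return An object of class `peak_gene_assignment`: list with `links`
#'   (`peak_id`, `gene_id`, `distance`), `nearest` (one row per assigned
#'   peak, keeping only its closest TSS, for analyses that want
#'   nearest-gene-only counts), `unassigned` (peak ids with no gene in
#'   range), `n_peaks` and `window`.
#' @export
assign_peaks_to_tss <- function(peaks, annotation, window = 2000) {
  if (window <= 0) stop("`window` must be > 0")
  links <- list()
  for (ch in intersect(unique(peaks$chrom), unique(annotation$chrom))) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    an <- annotation[annotation$chrom == ch, , drop = FALSE]
    an <- an[order(an$tss), , drop = FALSE]
    lo <- findInterval(pk$summit - window, an$tss, left.open = TRUE) + 1L
    hi <- findInterval(pk$summit + window, an$tss)
    n_each <- pmax(0L, hi - lo + 1L)
    if (!any(n_each > 0L)) next
    pi <- rep(seq_len(nrow(pk)), n_each)
    gi <- unlist(Map(function(a, b) if (b >= a) a:b else integer(0), lo, hi),
                 use.names = FALSE)
    d_genomic <- pk$summit[pi] - an$tss[gi]
    links[[length(links) + 1L]] <- data.frame(
      peak_id = pk$peak_id[pi], gene_id = an$gene_id[gi],
      distance = ifelse(an$strand[gi] == "+", d_genomic, -d_genomic),
      stringsAsFactors = FALSE)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(peak_id = character(0), gene_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  rownames(links) <- NULL
  nearest <- links[order(links$peak_id, abs(links$distance)), , drop = FALSE]
  nearest <- nearest[!duplicated(nearest$peak_id), , drop = FALSE]
  rownames(nearest) <- NULL
  out <- list(links = links, nearest = nearest,
              unassigned = setdiff(peaks$peak_id, links$peak_id),
              n_peaks = nrow(peaks), window = window)
  class(out) <- "peak_gene_assignment"
  out
}

#' @export
print.peak_gene_assignment <- function(x, ...) {
  cat(sprintf(paste0(
    "peak_gene_assignment (window %g bp): %d links, %d/%d peaks assigned ",
    "to %d genes\n"), x$window, nrow(x$links),
    x$n_peaks - length(x$unassigned), x$n_peaks,
    length(unique(x$links$gene_id))))
  invisible(x)
}

#' Summit-to-TSS distance distribution
#'
#' Bins the signed summit-TSS distances of an assignment into `bin_width`-bp
#' bins over `[-window, +window]`, smooths the counts with a centred kernel,
#' and reports the bin whose smoothed value is maximal (ties go to the bin
#' nearer zero). The default kernel is triangular (discrete binomial weights,
#' e.g. 1/4-1/2-1/4 at span 3), which preserves the location of a peak whose
#' spread is smaller than one bin; a flat boxcar average is available too.
#'
#' @param assignment A [assign_peaks_to_tss()] result.
#' @param bin_width Bin width in bp (default 100).
#' @param smooth_window Kernel span in bins (odd, default 3).
#' @param kernel `"triangular"` (default) or `"boxcar"`.
#' @return An object of class `distance_histogram`: list with `bin_edges`,
#'   `bin_centers`, `counts`, `smoothed` and `mode_bin_center`.
#' @export
distance_distribution <- function(assignment, bin_width = 100,
                                  smooth_window = 3,
                                  kernel = c("triangular", "boxcar")) {
  kernel <- match.arg(kernel)
  d <- assignment$links$distance
  if (length(d) == 0L)
    stop("assignment has no links; cannot build a distance distribution")
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("`smooth_window` must be a positive odd number of bins")
  window <- assignment$window
  edges <- seq(-window, window, by = bin_width)
  if (edges[length(edges)] < window) edges <- c(edges, window)
  n_bins <- length(edges) - 1L
  idx <- pmin(pmax(findInterval(d, edges), 1L), n_bins)  # right edge closed
  counts <- tabulate(idx, nbins = n_bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  h <- (smooth_window - 1L) / 2L
  wts <- if (kernel == "triangular") (h + 1) - abs(seq(-h, h))
         else rep(1, smooth_window)
  smoothed <- vapply(seq_len(n_bins), function(i) {
    j <- max(1L, i - h):min(n_bins, i + h)
    w <- wts[j - i + h + 1L]
    sum(counts[j] * w) / sum(w)
  }, numeric(1))
  best <- which(smoothed == max(smoothed))
  best <- best[order(abs(centers[best]), centers[best])][1]
  out <- list(bin_width = bin_width, bin_edges = edges,
              bin_centers = centers, counts = counts, smoothed = smoothed,
              mode_bin_center = centers[best])
  class(out) <- "distance_histogram"
  out
}

#' Peak intensity summary
#'
#' Reports the exact median intensity (lower of the two middle values for an
#' even count), the max/median ratio, the number of peaks exceeding ten times
#' the median, and a simple histogram on the log10 scale.
#'
#' @param peaks A [peak_set()] or any data.frame with an `intensity` column.
#' @param fold Outlier fold-change threshold (default 10).
#' @return List with `median`, `max_ratio`, `n_over_fold`, `fold` and
#'   `histogram` (data.frame of log10-intensity bins).
#' @export
intensity_summary <- function(peaks, fold = 10) {
  x <- peaks$intensity
  if (length(x) == 0L) stop("empty peak set: no intensities to summarize")
  v <- sort(x)
  n <- length(v)
  med <- if (n %% 2 == 1L) v[(n + 1L) / 2L] else v[n / 2L]
  hb <- graphics::hist(log10(x), breaks = "Sturges", plot = FALSE)
  list(median = med,
       max_ratio = max(x) / med,
       n_over_fold = sum(x > fold * med),
       fold = fold,
       histogram = data.frame(log10_mid = hb$mids, count = hb$counts))
}
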