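#' Construct a validated peak set
#'
#' A peak set is a data.frame of ChIP-seq peak calls with columns `chrom`,
#' `start`, `end` (0-based half-open), `summit` (absolute coordinate of the
#' peak's maximum-height location) and `intensity`, sorted by
#' `(chrom, summit)`. The summit is the identity key of a peak: duplicate
#' `(chrom, summit)` pairs within one set are rejected.
#'
#' @param df data.frame with the five peak columns (a `peak_id` column is
#'   added if absent).
#' @param replicate_id Identifier stored as an attribute and used to build
#'   default peak ids.
#' @return A data.frame of class `peak_set`.
#' @export
peak_set <- function(df, replicate_id = "rep") {
  required <- c("chrom", "start", "end", "summit", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!(df$start <= df$summit & df$summit < df$end))
  if (length(bad))
    stop("summit outside [start, end) for row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (any(df$intensity < 0))
    stop("negative intensities are not allowed")
  df <- df[order(df$chrom, df$summit), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "summit")])
  if (any(dup))
    stop("duplicate (chrom, summit) peaks in replicate '", replicate_id,
         "': e.g. ", df$chrom[dup][1], ":", df$summit[dup][1])
  if (is.null(df$peak_id))
    df$peak_id <- sprintf("%s_peak_%05d", replicate_id, seq_len(nrow(df)))
  rownames(df) <- NULL
  df <- df[, c("peak_id", required)]
  attr(df, "replicate_id") <- replicate_id
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Reconcile two replicate peak sets into Class A/B/C peaks
#'
#' Peaks from the two replicates whose summits lie within `max_dist` bp of
#' each other on the same chromosome are matched one-to-one, greedily by
#' ascending summit distance (ties broken by lower replicate-1 summit, then
#' lower replicate-2 summit). Matched pairs form Class A (one logical peak
#' per pair, represented by its replicate-1 member); unmatched replicate-1
#' peaks are Class B and unmatched replicate-2 peaks Class C. By
#' construction `|A| + |B| = |rep1|` and `|A| + |C| = |rep2|`.
#'
#' @param rep1,rep2 [peak_set()] data.frames.
#' @param max_dist Maximum summit distance in bp (default 200).
#' @return An object of class `peak_classification`: a list with `class_a`
#'   (matched pairs with representative rep1 coordinates, both summits and
#'   their distance), `class_b`, `class_c` (peak_set rows) and `max_dist`.
#' @export
classify_replicates <- function(rep1, rep2, max_dist = 200) {
  stopifnot_scalar_number(max_dist, "max_dist", min = 0)
  pairs <- candidate_pairs(rep1, rep2, max_dist)
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  keep <- logical(nrow(pairs))
  if (nrow(pairs)) {
    ord <- order(pairs$dist, pairs$summit1, pairs$summit2)
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used1[i] && !used2[j]) {
        used1[i] <- TRUE; used2[j] <- TRUE; keep[k] <- TRUE
      }
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  class_a <- data.frame(
    peak_id = rep1$peak_id[pairs$i],
    chrom = rep1$chrom[pairs$i],
    start = rep1$start[pairs$i], end = rep1$end[pairs$i],
    summit = rep1$summit[pairs$i], intensity = rep1$intensity[pairs$i],
    peak_id2 = rep2$peak_id[pairs$j], summit2 = rep2$summit[pairs$j],
    summit_distance = pairs$dist, stringsAsFactors = FALSE)
  class_a <- class_a[order(class_a$chrom, class_a$summit), , drop = FALSE]
  rownames(class_a) <- NULL
  out <- list(class_a = class_a,
              class_b = rep1[!used1, , drop = FALSE],
              class_c = rep2[!used2, , drop = FALSE],
              max_dist = max_dist)
  class(out) <- "peak_classification"
  out
}

# All (i, j, distance) candidates with same chrom and distance <= max_dist,
# found by interval lookup on the sorted rep2 summits.
candidate_pairs <- function(rep1, rep2, max_dist) {
  out <- list()
  for (ch in intersect(unique(rep1$chrom), unique(rep2$chrom))) {
    i1 <- which(rep1$chrom == ch)
    i2 <- which(rep2$chrom == ch)
    s2 <- rep2$summit[i2]                      # sorted within chrom
    lo <- findInterval(rep1$summit[i1] - max_dist, s2, left.open = TRUE) + 1L
    hi <- findInterval(rep1$summit[i1] + max_dist, s2)
    n_each <- pmax(0L, hi - lo + 1L)
    if (!any(n_each > 0L)) next
    ii <- rep(i1, n_each)
    jj <- i2[unlist(Map(function(a, b) if (b >= a) a:b else integer(0),
                        lo, hi), use.names = FALSE)]
    out[[length(out) + 1L]] <- data.frame(
      i = ii, j = jj,
      summit1 = rep1$summit[ii], summit2 = rep2$summit[jj],
      dist = abs(rep1$summit[ii] - rep2$summit[jj]))
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), summit1 = numeric(0),
                      summit2 = numeric(0), dist = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.peak_classification <- function(x, ...) {
  cat(sprintf(paste0(
    "peak_classification (max_dist = %g bp): %d Class A pairs, ",
    "%d Class B, %d Class C\n"),
    x$max_dist, nrow(x$class_a), nrow(x$class_b), nrow(x$class_c)))
  invisible(x)
}

#' Extract peak-centred sequences
#'
#' Returns the `flank` bp on each side of every peak's summit (a 2*`flank`
#' window, 0-based half-open `[summit - flank, summit + flank)`), truncated
#' with a warning where it runs off a chromosome end. Strand is taken as
#' given (+).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param peaks A [peak_set()] or the `class_a` table of a classification.
#' @param flank Flank size in bp (default 100, i.e. 200-bp regions).
#' @return A [Biostrings::DNAStringSet] named by `peak_id`.
#' @export
extract_peak_sequences <- function(genome, peaks, flank = 100) {
  stopifnot_scalar_number(flank, "flank", min = 0)
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  if (nrow(peaks) == 0L || flank == 0)
    return(stats::setNames(
      Biostrings::DNAStringSet(rep("", nrow(peaks))), peaks$peak_id))
  lens <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  from <- pmax(0, peaks$summit - flank)
  to <- pmin(lens, peaks$summit + flank)
  if (any(from > peaks$summit - flank | to < peaks$summit + flank))
    warning("some peak windows were truncated at chromosome ends")
  out <- vector("list", length(unique(peaks$chrom)))
  seqs <- Biostrings::DNAStringSet(rep("", nrow(peaks)))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    at <- IRanges::IRanges(start = from[idx] + 1L, end = to[idx])
    seqs[idx] <- Biostrings::extractAt(genome[[ch]], at)
  }
  names(seqs) <- peaks$peak_id
  seqs
}
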