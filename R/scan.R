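#' Composition-preserving sequence shuffle
#'
#' The default (`method = "mono"`) is a uniform random permutation of the
#' letters of each sequence, preserving the base multiset exactly; this is
#' the scramble used to build the empirical null for threshold calibration.
#' `method = "dinucleotide"` instead preserves the dinucleotide counts via a
#' random Eulerian path on the dinucleotide transition graph (the
#' Altschul-Erickson construction), for sequences where neighbour
#' correlations matter; it is offered as an option and is not used by the
#' default calibration.
#'
#' @param sequence Character vector (or DNAStringSet) of sequences.
#' @param seed Optional integer seed; when supplied the shuffle uses a local
#'   RNG stream and leaves the caller's RNG untouched.
#' @param method `"mono"` (default) or `"dinucleotide"`.
#' @return Character vector of shuffled sequences (names preserved).
#' @export
shuffle_sequence <- function(sequence, seed = NULL,
                             method = c("mono", "dinucleotide")) {
  method <- match.arg(method)
  sequence <- as_sequences(sequence)
  if (any(nchar(sequence) == 0L)) stop("cannot shuffle an empty sequence")
  one <- if (method == "mono") function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste0(ch[sample.int(length(ch))], collapse = "")
  } else dinuc_shuffle_one
  do_shuffle <- function() vapply(sequence, one, character(1))
  if (is.null(seed)) do_shuffle() else with_seed(seed, do_shuffle())
}

# Altschul-Erickson dinucleotide shuffle: sample uniform random "last edges"
# forming a tree into the terminal letter, randomize the remaining out-edges,
# and walk the resulting Eulerian path from the first letter.
dinuc_shuffle_one <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  letters_used <- unique(ch)
  last <- ch[n]
  edges <- split(ch[-1], ch[-n])       # out-edge targets per source letter
  verts <- names(edges)
  for (attempt in 1:100) {
    last_edge <- vapply(verts, function(v)
      edges[[v]][sample.int(length(edges[[v]]), 1L)], character(1))
    # every vertex (except the terminal) must reach `last` via last edges
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      seen <- character(0); cur <- v
      while (cur != last && !cur %in% seen) {
        seen <- c(seen, cur)
        if (!cur %in% verts) { break }
        cur <- last_edge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(paste0(ch[sample.int(n)], collapse = ""))  # degenerate
  ordered <- lapply(verts, function(v) {
    out <- edges[[v]]
    if (v %in% setdiff(verts, last)) {
      i <- match(last_edge[[v]], out)
      rest <- out[-i]
      c(rest[sample.int(length(rest))], out[i])
    } else out[sample.int(length(out))]
  })
  names(ordered) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- ordered[[cur]][used[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste0(res, collapse = "")
}

#' Calibrate a motif-call p-value threshold against scrambled sequences
#'
#' For each candidate threshold `t`, computes the fraction of real regions in
#' which the motif is called (sequence-level best-hit p < t) and the mean of
#' the same fraction over `n_shuffles` full scrambles of the regions. The
#' chosen threshold maximizes the difference between the two fractions, ties
#' going to the more stringent candidate. The default candidate grid spans
#' decade steps 1e-2 .. 1e-6 and includes 1e-4.
#'
#' @param pwm A [build_pwm()] object.
#' @param regions Character vector or DNAStringSet of region sequences.
#' @param n_shuffles Number of independent full scrambles (default 5).
#' @param candidates Candidate p-value thresholds (sorted descending).
#' @param seed Optional integer seed for the scrambles.
#' @param dist Optional precomputed [score_distribution()].
#' @return An object of class `calibration_result`: list with `motif_id`,
#'   `table` (threshold, frac_bound, frac_scrambled, difference),
#'   `chosen_threshold`, `n_shuffles`, `n_regions`.
#' @export
calibrate_threshold <- function(pwm, regions, n_shuffles = 5,
                                candidates = 10^-(2:6), seed = NULL,
                                dist = NULL) {
  regions <- as_sequences(regions)
  if (length(regions) < 1L) stop("need at least one region")
  candidates <- sort(candidates, decreasing = TRUE)
  if (is.null(dist)) dist <- score_distribution(pwm)

  frac_below <- function(p, t) mean(p < t, na.rm = TRUE)
  p_real <- scan_stats(pwm, regions, dist)$p_value
  p_shuf <- matrix(NA_real_, nrow = length(regions), ncol = n_shuffles)
  seeds <- if (is.null(seed)) rep(list(NULL), n_shuffles) else
    as.list(with_seed(seed, sample.int(2147483646L, n_shuffles)))
  for (k in seq_len(n_shuffles))
    p_shuf[, k] <- scan_stats(
      pwm, shuffle_sequence(regions, seed = seeds[[k]]), dist)$p_value

  tab <- data.frame(
    threshold = candidates,
    frac_bound = vapply(candidates, function(t) frac_below(p_real, t),
                        numeric(1)),
    frac_scrambled = vapply(candidates, function(t)
      mean(apply(p_shuf, 2, frac_below, t = t)), numeric(1)))
  tab$difference <- tab$frac_bound - tab$frac_scrambled
  chosen <- min(tab$threshold[tab$difference == max(tab$difference)])
  structure(list(motif_id = pwm$motif_id, table = tab,
                 chosen_threshold = chosen, n_shuffles = n_shuffles,
                 n_regions = length(regions)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration for '%s' (%d regions, %d scrambles):\n",
              x$motif_id, x$n_regions, x$n_shuffles))
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen threshold: %g\n", x$chosen_threshold))
  invisible(x)
}

#' Motif presence calls over a panel of PWMs
#'
#' Calls a motif present in a region when its sequence-level best-hit p-value
#' is below that motif's threshold. Multiple hits of one motif in a region
#' still count as a single presence (boolean semantics). Regions in which no
#' window is scorable (all N) get an `NA` row and are excluded from
#' downstream denominators.
#'
#' @param pwms Named list of [build_pwm()] objects.
#' @param regions Character vector or DNAStringSet of region sequences.
#' @param thresholds Named numeric vector of per-motif p-value thresholds (a
#'   single unnamed value is recycled to all motifs).
#' @param dists Optional named list of precomputed score distributions.
#' @return A logical regions x motifs matrix of class `motif_presence` with
#'   attributes `thresholds` and `scorable` (logical per region).
#' @export
scan_regions <- function(pwms, regions, thresholds, dists = NULL) {
  regions <- as_sequences(regions)
  ids <- names(pwms)
  if (is.null(ids) && length(pwms))
    ids <- vapply(pwms, `[[`, character(1), "motif_id")
  names(pwms) <- ids
  if (length(thresholds) == 1L && is.null(names(thresholds)))
    thresholds <- stats::setNames(rep(thresholds, length(ids)), ids)
  missing_t <- setdiff(ids, names(thresholds))
  if (length(missing_t))
    stop("no threshold supplied for motif(s): ",
         paste(missing_t, collapse = ", "))
  present <- matrix(NA, nrow = length(regions), ncol = length(ids),
                    dimnames = list(names(regions), ids))
  scorable <- rep(TRUE, length(regions))
  for (m in ids) {
    dist <- if (!is.null(dists)) dists[[m]] else NULL
    st <- scan_stats(pwms[[m]], regions, dist)
    present[, m] <- st$p_value < thresholds[[m]]
    scorable <- scorable & !is.na(st$p_value)
  }
  present[!scorable, ] <- NA
  structure(present, thresholds = thresholds[ids], scorable = scorable,
            class = c("motif_presence", "matrix"))
}
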