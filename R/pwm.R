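#' Build a position weight matrix from aligned sites
#'
#' Counts bases per position over equal-length aligned sites and converts to
#' probabilities with an additive pseudocount:
#' `p[i, b] = (count[i, b] + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param aligned_sites Character vector of equal-length ACGT sequences.
#' @param pseudocount Additive pseudocount (default 0.25).
#' @param background Length-4 base probability vector (A, C, G, T), summing
#'   to 1; default uniform.
#' @param motif_id Identifier stored with the matrix.
#' @return An object of class `pwm`: list with `motif_id`, `width`, `probs`
#'   (width x 4 matrix, columns A/C/G/T), `background`, `pseudocount`, and
#'   `log_odds` (log2 probs/background).
#' @export
build_pwm <- function(aligned_sites, pseudocount = 0.25,
                      background = rep(0.25, 4), motif_id = "motif") {
  if (length(aligned_sites) < 1L) stop("need at least one aligned site")
  w <- unique(nchar(aligned_sites))
  if (length(w) != 1L) stop("aligned sites must all have the same length")
  codes <- lapply(aligned_sites, seq_codes)
  for (s in seq_along(codes)) {
    bad <- which(is.na(codes[[s]]))
    if (length(bad))
      stop(sprintf("non-ACGT character in site %d at position %d",
                   s, bad[1]))
  }
  counts <- matrix(0, nrow = w, ncol = 4,
                   dimnames = list(NULL, DNA_BASES4))
  for (cd in codes)
    counts[cbind(seq_len(w), cd)] <- counts[cbind(seq_len(w), cd)] + 1
  probs <- (counts + pseudocount) /
    (length(aligned_sites) + 4 * pseudocount)
  new_pwm(probs, background, motif_id = motif_id, pseudocount = pseudocount)
}

new_pwm <- function(probs, background = rep(0.25, 4), motif_id = "motif",
                    pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("`probs` must have 4 columns (A, C, G, T)")
  colnames(probs) <- DNA_BASES4
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each PWM row must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("`background` must sum to 1")
  if (any(background <= 0))
    stop("`background` probabilities must be positive")
  background <- stats::setNames(as.numeric(background), DNA_BASES4)
  structure(list(motif_id = motif_id, width = nrow(probs), probs = probs,
                 background = background, pseudocount = pseudocount,
                 log_odds = log2(sweep(probs, 2, background, "/"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, consensus %s, max score %.2f bits\n",
              x$motif_id, x$width, pwm_consensus(x),
              sum(apply(x$log_odds, 1, max))))
  invisible(x)
}

pwm_consensus_bases <- function(pwm)
  DNA_BASES4[apply(pwm$probs, 1, which.max)]

#' Consensus sequence of a PWM
#' @param pwm A [build_pwm()] object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) paste0(pwm_consensus_bases(pwm), collapse = "")

#' Log-odds score of a single window
#'
#' Sums `log2(probs[i, base_i] / background[base_i])` over the window; on the
#' minus strand the window is reverse-complemented first. Windows containing
#' a non-ACGT character are unscorable and return `NA`.
#'
#' @param pwm A [build_pwm()] object.
#' @param window Character scalar, length exactly `pwm$width`.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits, or `NA` if unscorable.
#' @export
score_window <- function(pwm, window, strand = "+") {
  if (nchar(window) != pwm$width)
    stop(sprintf("window length %d does not match PWM width %d",
                 nchar(window), pwm$width))
  if (strand == "-") window <- revcomp(window)
  cd <- seq_codes(window)
  if (anyNA(cd)) return(NA_real_)
  sum(pwm$log_odds[cbind(seq_len(pwm$width), cd)])
}

#' Exact null distribution of the window score
#'
#' Computes the exact probability mass function of the PWM window score under
#' i.i.d. background bases, by column-wise convolution after rounding each
#' column's log-odds scores to multiples of `granularity`. The rounding error
#' of any window score is bounded by `width * granularity / 2`.
#'
#' @param pwm A [build_pwm()] object.
#' @param granularity Score resolution in bits (default 0.01).
#' @return An object of class `score_distribution`: list with `granularity`,
#'   `units` (integer score grid), `support` (= units * granularity, strictly
#'   increasing), `pmf` (sums to 1) and `tail` (upper-tail probabilities
#'   `P(score >= support)`).
#' @export
score_distribution <- function(pwm, granularity = 0.01) {
  if (granularity <= 0) stop("`granularity` must be > 0")
  li <- round(pwm$log_odds / granularity)      # width x 4, integer-valued
  if (any(!is.finite(li)))
    stop("PWM has zero-probability entries; use a positive pseudocount")
  bg <- pwm$background
  pmf <- 1; off <- 0                           # P(partial sum = off + idx - 1)
  for (i in seq_len(pwm$width)) {
    cs <- li[i, ]
    lo <- min(cs); hi <- max(cs)
    new <- numeric(length(pmf) + (hi - lo))
    for (b in 1:4) {
      sh <- cs[b] - lo
      new[(1 + sh):(length(pmf) + sh)] <-
        new[(1 + sh):(length(pmf) + sh)] + pmf * bg[b]
    }
    pmf <- new; off <- off + lo
  }
  units <- seq.int(off, length.out = length(pmf))
  keep <- pmf > 0                 # only achievable scores form the support
  units <- units[keep]; pmf <- pmf[keep]
  structure(list(granularity = granularity, units = units,
                 support = units * granularity, pmf = pmf,
                 tail = rev(cumsum(rev(pmf)))),
            class = "score_distribution")
}

# Rounded (integer-unit) scores of all windows of `codes` under the PWM,
# forward strand; NA where a window covers a non-ACGT base. Uses the same
# per-column rounding as score_distribution so observed scores land exactly
# on the null support.
window_units <- function(li, codes) {
  w <- nrow(li)
  n_win <- length(codes) - w + 1L
  if (n_win < 1L) return(numeric(0))
  sc <- numeric(n_win)
  for (j in seq_len(w))
    sc <- sc + li[j, codes[j:(j + n_win - 1L)]]
  sc
}

# Upper-tail probability of the distribution at integer units (vectorized).
tail_at_units <- function(dist, u) {
  idx <- length(dist$units) - findInterval(-u, rev(-dist$units)) + 1L
  ifelse(u > dist$units[length(dist$units)], 0,
         ifelse(u < dist$units[1], 1, dist$tail[pmax(idx, 1L)]))
}

# Per-sequence best-hit statistics for one PWM over both strands.
# Returns data.frame(best_units, p_site, m, p_value); NA rows = unscorable.
scan_stats <- function(pwm, seqs, dist = NULL, granularity = 0.01) {
  if (is.null(dist)) dist <- score_distribution(pwm, granularity)
  li <- round(pwm$log_odds / dist$granularity)
  li_rc <- li[pwm$width:1, 4:1, drop = FALSE]   # reverse complement scores
  colnames(li_rc) <- DNA_BASES4
  out <- data.frame(best_units = rep(NA_real_, length(seqs)),
                    p_site = NA_real_, m = 0L, p_value = NA_real_)
  for (k in seq_along(seqs)) {
    codes <- seq_codes(seqs[[k]])
    if (length(codes) < pwm$width)
      stop(sprintf("sequence %d is shorter (%d) than the PWM width (%d)",
                   k, length(codes), pwm$width))
    fw <- window_units(li, codes)
    rv <- window_units(li_rc, codes)
    scorable <- !is.na(fw)                      # same windows on both strands
    m <- 2L * sum(scorable)
    out$m[k] <- m
    if (m == 0L) next                           # all-N: unscorable sequence
    best <- max(fw[scorable], rv[scorable])
    p_site <- tail_at_units(dist, best)
    out$best_units[k] <- best
    out$p_site[k] <- p_site
    # Sidak correction over the m scorable windows
    out$p_value[k] <- -expm1(m * log1p(-p_site))
  }
  out
}

#' Best-hit p-value of a motif in a sequence
#'
#' Scores every window of the sequence on both strands, takes the best score,
#' and converts it to a single-site p-value `p_site = P(window score >= best)`
#' under the exact background [score_distribution()]. The sequence-level
#' p-value applies a Sidak correction over the `m` scorable windows:
#' `p = 1 - (1 - p_site)^m`, `m = 2 * (number of windows without N)`.
#'
#' @param pwm A [build_pwm()] object.
#' @param sequence Character scalar (or DNAString) of length >= width.
#' @param dist Optional precomputed [score_distribution()] for this PWM.
#' @param granularity Score resolution in bits when `dist` is not supplied.
#' @return List with `p_value`, `p_site`, `best_score` (bits), `m`. For an
#'   all-N sequence every field except `m` is `NA` ("unscorable"), never a
#'   silent 1.
#' @export
best_hit_pvalue <- function(pwm, sequence, dist = NULL, granularity = 0.01) {
  sequence <- as_sequences(sequence)
  if (length(sequence) != 1L) stop("`sequence` must be a single sequence")
  if (is.null(dist)) dist <- score_distribution(pwm, granularity)
  st <- scan_stats(pwm, sequence, dist)
  list(p_value = st$p_value[1], p_site = st$p_site[1],
       best_score = st$best_units[1] * dist$granularity, m = st$m[1])
}
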