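# Independent oracles used to freeze expected values: brute-force matching,
# full 4^w enumeration of the window-score null, set-operation Venn counts,
# and closed-form hypergeometric tails.

rand_dna <- function(n, len, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
           collapse = ""), character(1))
}

# Brute-force greedy matcher over the full distance matrix: repeatedly take
# the globally closest unused pair (ties: lower rep1 summit, then rep2).
oracle_classify <- function(rep1, rep2, max_dist) {
  n1 <- nrow(rep1); n2 <- nrow(rep2)
  d <- matrix(Inf, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    if (rep1$chrom[i] == rep2$chrom[j])
      d[i, j] <- abs(rep1$summit[i] - rep2$summit[j])
  d[d > max_dist] <- Inf
  pairs <- matrix(integer(0), ncol = 2)
  while (any(is.finite(d))) {
    cand <- which(d == min(d), arr.ind = TRUE)
    o <- order(rep1$summit[cand[, 1]], rep2$summit[cand[, 2]])
    i <- cand[o[1], 1]; j <- cand[o[1], 2]
    pairs <- rbind(pairs, c(i, j))
    d[i, ] <- Inf; d[, j] <- Inf
  }
  pairs
}

# Full enumeration of all 4^w windows with the same per-column score rounding
# as score_distribution; returns the exact upper-tail at each support unit.
oracle_enum_tail <- function(pwm, granularity = 0.01) {
  li <- round(pwm$log_odds / granularity)
  w <- pwm$width
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(idx))
  for (j in seq_len(w)) sc <- sc + li[j, idx[, j]]
  lp <- log(pwm$background)
  pr <- exp(rowSums(matrix(lp[idx], nrow = nrow(idx))))
  list(score_units = sc, prob = pr,
       tail_at = function(u) sum(pr[sc >= u]))
}

# Venn region counts by explicit set algebra over all membership patterns.
oracle_venn <- function(sets) {
  u <- unique(unlist(sets, use.names = FALSE))
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(pats) <- names(sets)
  pats$count <- apply(pats[, names(sets), drop = FALSE], 1, function(p) {
    sel <- u
    for (k in seq_along(sets))
      sel <- if (p[k]) intersect(sel, sets[[k]]) else setdiff(sel, sets[[k]])
    length(sel)
  })
  pats
}

# Exact hypergeometric upper tail P(X >= k) by direct summation.
oracle_hyper_tail <- function(k, K, N, n) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Random peak-set pair on a shared small coordinate space (distinct summits
# within each replicate).
random_peak_pair <- function(n1, n2, span = 3000, chroms = c("chr1", "chr2")) {
  mk <- function(n, id) {
    chrom <- sample(chroms, n, replace = TRUE)
    summit <- numeric(n)
    for (ch in unique(chrom)) {
      k <- sum(chrom == ch)
      summit[chrom == ch] <- sample(200:(200 + span), k)
    }
    peak_set(data.frame(chrom = chrom, start = summit - 100,
                        end = summit + 100, summit = summit,
                        intensity = round(stats::rlnorm(n, 3, 0.5), 4)),
             replicate_id = id)
  }
  list(rep1 = mk(n1, "rep1"), rep2 = mk(n2, "rep2"))
}

# Direct assignment-object constructor for histogram tests.
fake_assignment <- function(distances, window = 2000) {
  structure(list(links = data.frame(
    peak_id = sprintf("p%05d", seq_along(distances)),
    gene_id = rep("g", length(distances)), distance = distances,
    stringsAsFactors = FALSE),
    unassigned = character(0), n_peaks = length(distances),
    window = window),
    class = "peak_gene_assignment")
}

# Sharp test PWM with unique column maxima, given a consensus string.
sharp_pwm <- function(consensus, p_max = 0.85, motif_id = "test") {
  cd <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - p_max) / 3, nrow = length(cd), ncol = 4)
  probs[cbind(seq_along(cd), cd)] <- p_max
  regulonscan:::new_pwm(probs, motif_id = motif_id)
}
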