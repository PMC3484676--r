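test_that("PWM construction follows the pseudocount rule and validates input", {
  # single site, zero pseudocount: unit probability rows
  p1 <- build_pwm("ACGT", pseudocount = 0)
  expect_equal(p1$probs, matrix(c(1, 0, 0, 0,
                                  0, 1, 0, 0,
                                  0, 0, 1, 0,
                                  0, 0, 0, 1),
                                nrow = 4, byrow = TRUE,
                                dimnames = list(NULL, c("A", "C", "G", "T"))))
  # two AA sites, pseudocount 0.25: prob(A) = 2.25 / 3 = 0.75
  p2 <- build_pwm(c("AA", "AA"))
  expect_equal(unname(p2$probs[, "A"]), c(0.75, 0.75))
  expect_equal(unname(p2$probs[, "C"]), c(1, 1) / 12)

  expect_error(build_pwm(c("ACGT", "ACNT")), "site 2 at position 3")
  expect_error(build_pwm(c("ACGT", "ACG")), "same length")
  expect_error(build_pwm(character(0)), "at least one")

  # rows always sum to 1
  set.seed(3)
  sites <- rand_dna(15, 9)
  expect_equal(unname(rowSums(build_pwm(sites)$probs)), rep(1, 9))
})

test_that("window scoring matches the direct log-odds sum on both strands", {
  pwms <- synthetic_motifs()
  # uniform PWM against uniform background scores 0 everywhere
  unif <- regulonscan:::new_pwm(matrix(0.25, 5, 4), motif_id = "unif")
  expect_equal(score_window(unif, "ACGTA"), 0)
  expect_equal(score_window(unif, "TTTTT"), 0)

  # consensus attains the maximum attainable score
  e2f <- pwms$E2F
  expect_equal(score_window(e2f, pwm_consensus(e2f)),
               sum(apply(e2f$log_odds, 1, max)))

  # direct-sum oracle on random windows, forward and reverse
  set.seed(14)
  for (w in rand_dna(10, 8)) {
    cd <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    manual <- sum(e2f$log_odds[cbind(1:8, cd)])
    expect_equal(score_window(e2f, w), manual, tolerance = 1e-12)
    expect_equal(score_window(e2f, w, strand = "-"),
                 score_window(e2f, regulonscan:::revcomp(w)))
  }

  expect_error(score_window(e2f, "ACGT"), "width")
  expect_true(is.na(score_window(e2f, "ACGTNCGT")))
})

test_that("the exact score distribution equals full enumeration", {
  pwms <- synthetic_motifs()
  # width-1: pmf is the background reweighted onto the 4 column scores
  w1 <- regulonscan:::new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4),
                              motif_id = "w1")
  d1 <- score_distribution(w1)
  expect_equal(sum(d1$pmf), 1, tolerance = 1e-12)
  expect_equal(length(d1$support), 2)   # three columns share one score
  expect_equal(d1$pmf[order(d1$support)], c(0.75, 0.25))

  # enumeration oracle at width 8 (DREF) and a random width-5 PWM
  for (pwm in list(pwms$DREF, build_pwm(rand_dna(12, 5), motif_id = "r5"))) {
    d <- score_distribution(pwm)
    en <- oracle_enum_tail(pwm)
    expect_equal(d$tail, vapply(d$units, en$tail_at, numeric(1)),
                 tolerance = 1e-9)
    expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
    expect_true(all(diff(d$support) > 0))
  }
})

test_that("best-hit p-values follow the exact null and the Sidak correction", {
  pwms <- synthetic_motifs()
  e2f <- pwms$E2F
  expect_error(best_hit_pvalue(e2f, "ACGT"), "shorter")

  # consensus alone: p_site equals the product of background probabilities of
  # the consensus bases (unique column maxima), here 0.25^8
  hit <- best_hit_pvalue(e2f, pwm_consensus(e2f))
  expect_equal(hit$p_site, 0.25^8, tolerance = 1e-12)
  expect_equal(hit$m, 2)
  expect_equal(hit$p_value, 1 - (1 - 0.25^8)^2, tolerance = 1e-12)

  # consensus with a 2-bp pad is still significant at 1e-4
  padded <- paste0("AC", pwm_consensus(e2f))
  expect_lt(best_hit_pvalue(e2f, padded)$p_value, 1e-4)

  # all-N sequences are unscorable, never silently p = 1
  nn <- best_hit_pvalue(e2f, paste0(rep("N", 30), collapse = ""))
  expect_true(is.na(nn$p_value))
  expect_equal(nn$m, 0)

  # N windows shrink m
  seqN <- paste0(pwm_consensus(e2f), "NNNN", pwm_consensus(e2f))
  hN <- best_hit_pvalue(e2f, seqN)
  expect_equal(hN$m, 4)   # 2 scorable offsets x 2 strands
})

test_that("shuffles preserve composition and are uniform over permutations", {
  expect_equal(unname(shuffle_sequence("AAAA", seed = 1)), "AAAA")
  set.seed(5)
  s <- rand_dna(1, 300)
  sh <- shuffle_sequence(s)
  expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_error(shuffle_sequence(""), "empty")

  # all 24 permutations of ACGT within the chi-square 99% band
  set.seed(6)
  draws <- replicate(3000, shuffle_sequence("ACGT"))
  tab <- table(draws)
  expect_equal(length(tab), 24)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # seeded shuffles are reproducible and do not disturb the caller RNG
  set.seed(7); before <- .Random.seed
  a <- shuffle_sequence(s, seed = 99)
  expect_identical(.Random.seed, before)
  expect_identical(a, shuffle_sequence(s, seed = 99))
})

test_that("threshold calibration discriminates planted from scrambled", {
  pwms <- synthetic_motifs()
  ram <- pwms$RAM

  # deterministic tie-break: no hits at any candidate -> most stringent wins
  set.seed(21)
  quiet <- rand_dna(10, 100)
  cal0 <- calibrate_threshold(ram, quiet, candidates = c(1e-5, 1e-6),
                              seed = 1)
  expect_equal(sum(cal0$table$frac_bound), 0)
  expect_equal(sum(cal0$table$frac_scrambled), 0)
  expect_equal(cal0$chosen_threshold, 1e-6)

  # default candidate grid includes the 1e-4 decade step
  expect_true(1e-4 %in% eval(formals(calibrate_threshold)$candidates))

  # planted case: half the regions carry the exact consensus
  set.seed(22)
  regions <- rand_dna(200, 200)
  cons <- pwm_consensus(ram)
  for (i in 1:100) {
    off <- sample(200 - nchar(cons) + 1, 1)
    substr(regions[i], off, off + nchar(cons) - 1) <- cons
  }
  cal <- calibrate_threshold(ram, regions, seed = 2)
  cand <- cal$table$threshold
  expect_false(cal$chosen_threshold %in% cand[c(1, length(cand))])
  expect_gte(cal$table$frac_bound[cand == cal$chosen_threshold], 0.5)
  expect_lte(cal$table$frac_scrambled[cand == cal$chosen_threshold], 0.05)

  # difference curve vanishes at both extremes of the threshold range
  cal_ext <- calibrate_threshold(ram, regions, seed = 3,
                                 candidates = c(1 - 1e-12, 10^-(2:6), 1e-300))
  tab <- cal_ext$table
  expect_lt(abs(tab$difference[tab$threshold > 0.5]), 0.02)
  expect_equal(tab$difference[tab$threshold == 1e-300], 0)
})

test_that("scrambled false-call rate matches the Sidak null rate", {
  ram <- synthetic_motifs()$RAM
  t <- 1e-3
  set.seed(33)
  regions <- rand_dna(100, 150)
  d <- score_distribution(ram)
  hits <- 0L; total <- 0L
  for (k in 1:200) {
    p <- regulonscan:::scan_stats(ram, shuffle_sequence(regions), d)$p_value
    hits <- hits + sum(p < t); total <- total + length(p)
  }
  expect_identical(total, 20000L)
  # the Sidak-corrected p is ~uniform for this non-palindromic motif, so the
  # false-call rate at threshold t converges to t (3-SD band, plus a small
  # allowance for the residual overlapping-window dependence)
  expect_lt(abs(hits / total - t), 3 * sqrt(t * (1 - t) / total) + t / 3)
})

test_that("presence calls are boolean, strand-symmetric and N-aware", {
  pwms <- synthetic_motifs()
  th <- c(E2F = 1e-2, DREF = 1e-2, FOXJ2 = 1e-2, RAM = 1e-3)
  set.seed(44)
  regions <- rand_dna(30, 200)
  cons <- pwm_consensus(pwms$E2F)
  substr(regions[1], 50, 57) <- cons
  # duplicating a planted site cannot change a presence call
  dup <- regions
  substr(dup[1], 100, 107) <- cons
  pm <- scan_regions(pwms, regions, th)
  pm_dup <- scan_regions(pwms, dup, th)
  expect_true(pm[1, "E2F"])
  expect_identical(unclass(pm), unclass(pm_dup))

  # reverse-complementing every region leaves presence unchanged
  pm_rc <- scan_regions(pwms, regulonscan:::revcomp(regions), th)
  expect_identical(unname(unclass(pm)), unname(unclass(pm_rc)))

  # unscorable regions are flagged as NA rows and excluded downstream
  regions_na <- c(regions, paste0(rep("N", 200), collapse = ""))
  pm_na <- scan_regions(pwms, regions_na, th)
  expect_true(all(is.na(pm_na[31, ])))
  expect_false(attr(pm_na, "scorable")[31])
  cc <- constellation_counts(pm_na)
  expect_equal(cc$n_regions, 30)

  # empty motif panel: zero columns
  pm0 <- scan_regions(list(), regions[1:3], numeric(0))
  expect_equal(ncol(pm0), 0)

  # per-motif thresholds must cover the panel
  expect_error(scan_regions(pwms, regions[1:2], c(E2F = 1e-2)), "threshold")
})

test_that("dinucleotide shuffling preserves doublet counts", {
  dinuc_counts <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(81)
  for (s in rand_dna(10, 120)) {
    sh <- unname(shuffle_sequence(s, seed = 5, method = "dinucleotide"))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 120, 120), substr(s, 120, 120))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
  }
  # and it actually permutes something for a heterogeneous sequence
  s <- paste0(rand_dna(1, 300))
  expect_false(identical(shuffle_sequence(s, seed = 1,
                                          method = "dinucleotide"),
                         unname(s)))
})
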