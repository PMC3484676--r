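# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic per-purpose substream seeds: changing one stage's parameters
# must not perturb another stage's draws, so each stage re-seeds from its own
# derived seed. Derivation goes through the Mersenne-Twister so nearby master
# seeds give unrelated substreams. Stage seeds stay below 2^31.
stage_seed <- function(seed, stage) {
  stages <- c(genome = 1L, tss = 2L, plants = 3L, peaks = 4L,
              background = 5L, shuffle = 6L, orthologs = 7L, categories = 8L,
              conditions = 9L)
  idx <- stages[[match.arg(stage, names(stages))]]
  with_seed(as.integer(seed), sample.int(2147483646L, 16L))[idx]
}

# Map a DNA string to integer codes A=1 C=2 G=3 T=4, NA for anything else.
DNA_BASES4 <- c("A", "C", "G", "T")

.code_table <- local({
  tbl <- rep(NA_integer_, 128L)
  tbl[utf8ToInt("A")] <- 1L; tbl[utf8ToInt("a")] <- 1L
  tbl[utf8ToInt("C")] <- 2L; tbl[utf8ToInt("c")] <- 2L
  tbl[utf8ToInt("G")] <- 3L; tbl[utf8ToInt("g")] <- 3L
  tbl[utf8ToInt("T")] <- 4L; tbl[utf8ToInt("t")] <- 4L
  tbl
})

seq_codes <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(NA_integer_, length(v))
  ok <- v >= 1L & v <= 128L
  out[ok] <- .code_table[v[ok]]
  out
}

# Coerce sequence input (character vector, DNAString(Set)) to a named
# character vector.
as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString"))
    x <- as.character(x)
  if (!is.character(x))
    stop("sequences must be a character vector or a Biostrings DNAStringSet")
  if (is.null(names(x)) && length(x) > 0)
    names(x) <- sprintf("region_%04d", seq_along(x))
  x
}

revcomp <- function(s) {
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1), USE.NAMES = FALSE)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}
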