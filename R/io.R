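# File-format boundary: peak TSV / narrowPeak, TSS annotation (BED6 / GFF3
# via rtracklayer), MEME-minimal and plain-matrix PWMs, and the long-format
# TSVs consumed by the enrichment and conservation modules.

#' Read a peak-call table
#'
#' Two dialects are supported: the pipeline's 5-column peak TSV
#' (`chrom start end summit intensity`, header line, 0-based half-open,
#' absolute summit) and narrowPeak (summit stored as an offset from `start`
#' in column 10; `-1` offsets are rejected). Malformed lines are reported
#' with their line numbers.
#'
#' @param path File path.
#' @param dialect `"peaktsv"` or `"narrowpeak"`.
#' @param replicate_id Identifier for the resulting [peak_set()].
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("peaktsv", "narrowpeak"),
                       replicate_id = sub("\\.[^.]*$", "", basename(path))) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "peaktsv") {
    if (length(lines) == 0L) stop("empty peak file (missing header): ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("chrom", "start", "end", "summit", "intensity")
    if (!all(need %in% header))
      stop("peak TSV header must contain: ", paste(need, collapse = ", "))
    body <- lines[-1]
    n_col <- length(header)
    offset <- 1L
  } else {
    body <- lines
    n_col <- 10L
    offset <- 0L
  }
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_col)
  if (length(bad))
    stop("malformed line(s) (expected ", n_col, " fields) at: ",
         paste(utils::head(bad + offset, 10), collapse = ", "))
  if (length(body) == 0L) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), summit = numeric(0),
                     intensity = numeric(0), stringsAsFactors = FALSE)
    return(peak_set(df, replicate_id))
  }
  m <- do.call(rbind, fields)
  if (dialect == "peaktsv") {
    colnames(m) <- header
    df <- data.frame(chrom = m[, "chrom"],
                     start = as.numeric(m[, "start"]),
                     end = as.numeric(m[, "end"]),
                     summit = as.numeric(m[, "summit"]),
                     intensity = as.numeric(m[, "intensity"]),
                     stringsAsFactors = FALSE)
    if ("peak_id" %in% header) df$peak_id <- m[, "peak_id"]
  } else {
    summit_off <- as.numeric(m[, 10])
    if (any(summit_off < 0))
      stop("narrowPeak line(s) without a summit (offset -1) at: ",
           paste(utils::head(which(summit_off < 0), 10), collapse = ", "))
    df <- data.frame(chrom = m[, 1],
                     start = as.numeric(m[, 2]),
                     end = as.numeric(m[, 3]),
                     summit = as.numeric(m[, 2]) + summit_off,
                     intensity = as.numeric(m[, 7]),
                     stringsAsFactors = FALSE)
  }
  nn <- which(!stats::complete.cases(df[, c("start", "end", "summit",
                                            "intensity")]))
  if (length(nn))
    stop("non-numeric coordinate/intensity at line(s): ",
         paste(utils::head(nn + offset, 10), collapse = ", "))
  peak_set(df, replicate_id)
}

#' Write a peak set as peak TSV
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- as.data.frame(peaks)[, c("peak_id", "chrom", "start", "end",
                                 "summit", "intensity")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a replicate classification as TSV
#'
#' One row per logical peak with a `class` column in `{A, B, C}`; Class A
#' rows carry both source summits and their distance.
#'
#' @param classification A [classify_replicates()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  a <- classification$class_a
  mk <- function(df, cls) {
    out <- data.frame(peak_id = df$peak_id, class = cls, chrom = df$chrom,
                      start = df$start, end = df$end, summit = df$summit,
                      intensity = df$intensity, stringsAsFactors = FALSE)
    out$summit2 <- if (cls == "A") df$summit2 else NA
    out$summit_distance <- if (cls == "A") df$summit_distance else NA
    out
  }
  out <- rbind(mk(a, "A"), mk(classification$class_b, "B"),
               mk(classification$class_c, "C"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation from GFF3 or BED
#'
#' GFF3: `gene` features (or all features if none are typed `gene`); the TSS
#' is the strand-aware 5' end. BED (6 columns): width-1 records are taken as
#' the TSS itself, wider records as gene spans whose strand-aware 5' end is
#' used. Coordinates are returned 0-based.
#'
#' @param path File path (`.gff3`/`.gff` or `.bed`).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  tss <- ifelse(IRanges::width(gr) == 1L, GenomicRanges::start(gr) - 1L,
                ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr) - 1L))
  ids <- gr$ID %||% gr$name %||% sprintf("gene%05d", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             tss = as.numeric(tss), strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a TSS annotation
#'
#' `format = "bed"` writes 6-column BED with width-1 records at the TSS
#' (0-based half-open); `format = "gff3"` writes 1-based inclusive `gene`
#' features.
#'
#' @param annotation TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_tss <- function(annotation, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.frame(annotation$chrom, annotation$tss, annotation$tss + 1,
                     annotation$gene_id, 0, annotation$strand)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tregulonscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       annotation$chrom, annotation$tss + 1,
                       annotation$tss + 1, annotation$strand,
                       annotation$gene_id))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and the
#' optional `Background letter frequencies` line. Probability rows are
#' re-normalized only within 1e-6 tolerance; anything further off errors.
#'
#' @param path File path.
#' @param background Optional length-4 background overriding the file's.
#' @return Named list of [build_pwm()] objects.
#' @export
read_pwms_meme <- function(path, background = NULL) {
  lines <- readLines(path)
  bg <- background
  if (is.null(bg)) {
    bi <- grep("^Background letter frequencies", lines)
    if (length(bi)) {
      tok <- strsplit(trimws(lines[bi[1] + 1L]), "\\s+")[[1]]
      bg <- as.numeric(tok[c(2, 4, 6, 8)])
    } else bg <- rep(0.25, 4)
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hi <- grep("^letter-probability matrix", lines[s:length(lines)])[1]
    if (is.na(hi)) stop("MOTIF ", id, " lacks a letter-probability matrix")
    hline <- lines[s + hi - 1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hline))
    rows <- lines[(s + hi):(s + hi + w - 1L)]
    probs <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(probs) != 4L || anyNA(probs))
      stop("malformed probability rows for MOTIF ", id)
    if (any(abs(rowSums(probs) - 1) > 1e-6))
      stop("probability rows of MOTIF ", id, " do not sum to 1")
    probs <- probs / rowSums(probs)
    out[[id]] <- new_pwm(probs, bg, motif_id = id)
  }
  out
}

#' Write PWMs in MEME minimal motif format
#' @param pwms Named list of [build_pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwms_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3],
                     bg[4]), "")
  for (p in pwms) {
    lines <- c(lines, sprintf("MOTIF %s", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width),
               apply(p$probs, 1, function(r)
                 sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from a plain whitespace matrix
#'
#' One row per position, four columns (A C G T); `#`-prefixed comment lines
#' are ignored. Rows of probabilities (summing to 1) are used as is; rows of
#' counts are converted with [build_pwm()]'s pseudocount rule.
#'
#' @param path File path.
#' @param motif_id Identifier for the PWM.
#' @param pseudocount Pseudocount applied when the file holds counts.
#' @param background Length-4 background probabilities.
#' @return A [build_pwm()] object.
#' @export
read_pwm_matrix <- function(path, motif_id = basename(path),
                            pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- do.call(rbind, lapply(lines, function(r)
    as.numeric(strsplit(r, "\\s+")[[1]])))
  if (ncol(m) != 4L || anyNA(m))
    stop("expected 4 numeric columns (A C G T) in ", path)
  if (all(abs(rowSums(m) - 1) < 1e-6))
    return(new_pwm(m / rowSums(m), background, motif_id = motif_id))
  n <- rowSums(m)
  probs <- (m + pseudocount) / (n + 4 * pseudocount)
  new_pwm(probs, background, motif_id = motif_id,
          pseudocount = pseudocount)
}

#' Write a motif presence matrix as 0/1 TSV
#' @param presence A [scan_regions()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence <- function(presence, path) {
  mat <- unclass(presence) * 1L
  df <- data.frame(region_id = rownames(presence), mat)
  colnames(df) <- c("region_id", colnames(presence))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format two-column TSV (with header) as a data.frame
#'
#' Used for gene-category maps (`gene_id`, `category`), ortholog links
#' (`fly_id`, `human_id[, family_id]`) and long-format condition sets
#' (`condition`, `gene_id`).
#'
#' @param path File path.
#' @return data.frame with the file's columns.
#' @export
read_tsv_map <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)

#' Read per-condition bound-gene sets
#'
#' Accepts either one long-format TSV with header columns `condition` and
#' `gene_id`, or several per-condition TSVs (single `gene_id` column; the
#' condition is the file name without extension).
#'
#' @param paths One or more file paths.
#' @return Named list of character vectors.
#' @export
read_condition_sets <- function(paths) {
  out <- list()
  for (p in paths) {
    df <- read_tsv_map(p)
    if (all(c("condition", "gene_id") %in% names(df))) {
      sets <- split(df$gene_id, df$condition)
      out[names(sets)] <- lapply(sets, unique)
    } else if ("gene_id" %in% names(df)) {
      out[[sub("\\.[^.]*$", "", basename(p))]] <- unique(df$gene_id)
    } else {
      stop("condition file needs either (condition, gene_id) or gene_id: ", p)
    }
  }
  out
}

#' Load a generator configuration from a flat-key YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; the two per-motif
#' frequency maps are given as named YAML mappings. Unknown keys error.
#'
#' @param path YAML file path.
#' @return A [synthetic_config()].
#' @export
synthetic_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (f in c("motif_plant_freqs", "motif_background_freqs"))
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  do.call(synthetic_config, vals)
}
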