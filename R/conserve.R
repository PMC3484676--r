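#' Build an ortholog map from fly-human links
#'
#' An ortholog map is a data.frame of `fly_id`, `human_id`, `family_id`
#' links. When no family ids are supplied, families are taken as the
#' connected components of the bipartite fly-human link graph, which matches
#' the "orthologous family" semantics without requiring curated ids.
#'
#' @param links data.frame with columns `fly_id`, `human_id` and optionally
#'   `family_id`.
#' @return A data.frame of class `ortholog_map`.
#' @export
ortholog_map <- function(links) {
  need <- c("fly_id", "human_id")
  if (!all(need %in% names(links)))
    stop("ortholog links need columns fly_id and human_id")
  links <- unique(links[, intersect(c(need, "family_id"), names(links))])
  if (is.null(links$family_id)) {
    g <- igraph::graph_from_edgelist(
      cbind(paste0("fly:", links$fly_id), paste0("hs:", links$human_id)),
      directed = FALSE)
    comp <- igraph::components(g)$membership
    links$family_id <- sprintf("fam%04d", comp[paste0("fly:", links$fly_id)])
  }
  rownames(links) <- NULL
  class(links) <- c("ortholog_map", "data.frame")
  links
}

#' Map fly target genes to their human orthologs
#'
#' @param fly_targets Character vector of fly gene ids.
#' @param map An [ortholog_map()].
#' @return List with `human_genes` (sorted union of orthologs),
#'   `multiplicity` (per-fly-gene ortholog count for mapped genes) and
#'   `unmapped` (fly targets with no ortholog).
#' @export
map_fly_to_human <- function(fly_targets, map) {
  fly_targets <- unique(fly_targets)
  hit <- map[map$fly_id %in% fly_targets, , drop = FALSE]
  mult <- table(factor(hit$fly_id, levels = intersect(fly_targets,
                                                      hit$fly_id)))
  list(human_genes = sort(unique(hit$human_id)),
       multiplicity = data.frame(fly_id = names(mult),
                                 n_orthologs = as.integer(mult),
                                 stringsAsFactors = FALSE),
       unmapped = setdiff(fly_targets, hit$fly_id))
}

#' Ortholog families bound in both species
#'
#' A family qualifies if at least one of its fly members is in `fly_bound`
#' AND at least one of its human members is in `human_bound`.
#'
#' @param fly_bound,human_bound Character vectors of bound gene ids.
#' @param map An [ortholog_map()].
#' @return Sorted character vector of qualifying family ids.
#' @export
family_bound_in_both <- function(fly_bound, human_bound, map) {
  fly_fams <- unique(map$family_id[map$fly_id %in% fly_bound])
  hs_fams <- unique(map$family_id[map$human_id %in% human_bound])
  sort(intersect(fly_fams, hs_fams))
}

#' Venn partition of up to five gene sets
#'
#' Counts the genes in every intersection region (membership pattern) of the
#' given sets; the counts always sum to the size of the union.
#'
#' @param sets Named list of character vectors (2-5 sets).
#' @return data.frame with one logical membership column per set plus
#'   `count`, one row per non-empty region plus the all-FALSE row omitted.
#' @export
venn_partition <- function(sets) {
  if (length(sets) > 5L)
    stop("more than 5 sets in one Venn request; split the comparison")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste0(as.integer(r), collapse = ""))
  patterns <- unique(key)
  out <- do.call(rbind, lapply(patterns, function(p) {
    row <- as.data.frame(t(strsplit(p, "")[[1]] == "1"))
    names(row) <- names(sets)
    row$count <- sum(key == p)
    row
  }))
  out[order(-rowSums(out[, names(sets), drop = FALSE])), , drop = FALSE]
}

#' Overlap of a gene set with per-condition bound sets
#'
#' For each condition (e.g. RB or p130 binding in growing, quiescent or
#' senescent cells), the overlap with `setA` (typically the human orthologs
#' of the fly-bound genes); pairwise fractions are reported per condition and
#' a multi-way Venn partition can be requested for up to four conditions at
#' a time via [venn_partition()].
#'
#' @param setA Character vector (nonempty).
#' @param conditions Named list of character vectors of bound human genes.
#' @return data.frame with per-condition `n_condition`, `n_overlap`,
#'   `frac_of_A` and `frac_of_condition`.
#' @export
overlap_table <- function(setA, conditions) {
  setA <- unique(setA)
  if (length(setA) == 0L) stop("`setA` is empty")
  if (is.null(names(conditions)))
    stop("`conditions` must be a named list")
  rows <- lapply(names(conditions), function(cn) {
    s <- unique(conditions[[cn]])
    ov <- length(intersect(setA, s))
    data.frame(condition = cn, n_condition = length(s), n_overlap = ov,
               frac_of_A = ov / length(setA),
               frac_of_condition = if (length(s)) ov / length(s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric category enrichment of a gene subset
#'
#' For each category, the fold enrichment of the category inside `subset`
#' relative to `universe`, an upper-tail hypergeometric p-value, a
#' Benjamini-Hochberg q-value across categories, a lower-tail (depletion)
#' p-value, and a depletion flag when fold < 1.
#'
#' @param subset,universe Character vectors of gene ids; `subset` must be
#'   contained in `universe`.
#' @param categories data.frame with columns `gene_id`, `category`.
#' @return data.frame with one row per category: `category`, `n_universe`,
#'   `n_subset`, `fold`, `p_enrich`, `q_enrich`, `p_deplete`, `depleted`.
#' @export
category_enrichment <- function(subset, universe, categories) {
  subset <- unique(subset); universe <- unique(universe)
  if (!all(subset %in% universe))
    stop("`subset` is not contained in `universe`")
  N <- length(universe); n <- length(subset)
  cats <- split(categories$gene_id, categories$category)
  rows <- lapply(names(cats), function(cn) {
    members <- intersect(unique(cats[[cn]]), universe)
    K <- length(members)
    k <- length(intersect(members, subset))
    fold <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
    data.frame(category = cn, n_universe = K, n_subset = k, fold = fold,
               p_enrich = stats::phyper(k - 1, K, N - K, n,
                                        lower.tail = FALSE),
               p_deplete = stats::phyper(k, K, N - K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_enrich <- stats::p.adjust(out$p_enrich, method = "BH")
  out$depleted <- !is.na(out$fold) & out$fold < 1
  out[, c("category", "n_universe", "n_subset", "fold", "p_enrich",
          "q_enrich", "p_deplete", "depleted")]
}

#' Simulate a fly-to-human ortholog map with known fan-out
#'
#' Convenience generator for the conservation workflow: each fly gene gets
#' 0-`max_orthologs` human orthologs (fan-out drawn from `fanout_probs`), and
#' a configurable fraction of families additionally share human genes so that
#' multi-gene families exist. Purely synthetic; ids are opaque.
#'
#' @param fly_genes Character vector of fly gene ids.
#' @param fanout_probs Probabilities of 0, 1, 2, ... orthologs per fly gene.
#' @param seed Integer seed.
#' @return An [ortholog_map()].
#' @export
simulate_ortholog_map <- function(fly_genes,
                                  fanout_probs = c(0.15, 0.55, 0.2, 0.1),
                                  seed = 1L) {
  with_seed(seed, {
    fan <- sample(seq_along(fanout_probs) - 1L, length(fly_genes),
                  replace = TRUE, prob = fanout_probs)
    fly <- rep(fly_genes, fan)
    if (length(fly) == 0L)
      return(ortholog_map(data.frame(fly_id = character(0),
                                     human_id = character(0))))
    human <- sprintf("HS_%05d", seq_along(fly))
    ortholog_map(data.frame(fly_id = fly, human_id = human,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-condition human bound-gene sets
#'
#' Emulates published per-condition binding calls for two corepressor
#' factors: each factor binds a stable core subset of the supplied genes
#' (its targets are largely the same across cellular conditions), and each
#' condition adds a small condition-specific fringe plus bound genes outside
#' the input set. Conditions of one factor therefore overlap heavily, as
#' multi-condition occupancy maps do.
#'
#' @param human_genes Character vector of human gene ids.
#' @param core_rates Named numeric vector: per-factor probability that a gene
#'   belongs to the factor's stable core.
#' @param conditions Named list: per-factor character vector of condition
#'   labels; output names are `<factor>_<condition>`.
#' @param extra_rate Per-condition probability that a non-core gene is bound
#'   in that condition only.
#' @param n_extra Number of additional bound genes outside `human_genes`.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
simulate_condition_sets <- function(human_genes,
                                    core_rates = c(RB = 0.38, p130 = 0.55),
                                    conditions = list(
                                      RB = c("growing", "quiescent",
                                             "senescent"),
                                      p130 = c("quiescent", "senescent")),
                                    extra_rate = 0.05, n_extra = 200L,
                                    seed = 1L) {
  stopifnot(all(names(conditions) %in% names(core_rates)))
  with_seed(seed, {
    out <- list()
    for (fac in names(conditions)) {
      core <- human_genes[stats::runif(length(human_genes)) <
                            core_rates[[fac]]]
      for (cond in conditions[[fac]]) {
        fringe <- setdiff(human_genes, core)
        fringe <- fringe[stats::runif(length(fringe)) < extra_rate]
        extra <- sprintf("HSX_%05d", sample.int(10 * n_extra, n_extra))
        out[[paste(fac, cond, sep = "_")]] <- unique(c(core, fringe, extra))
      }
    }
    out
  })
}

#' Simulate a gene-to-category map
#'
#' Assigns each gene to one of `n_categories` generic categories (plus
#' possible multi-membership at `multi_rate`), for exercising the
#' per-category motif and enrichment tables.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_categories Number of categories.
#' @param multi_rate Probability a gene gets a second category.
#' @param seed Integer seed.
#' @return data.frame with columns `gene_id`, `category`.
#' @export
simulate_gene_categories <- function(gene_ids, n_categories = 8L,
                                     multi_rate = 0.1, seed = 1L) {
  labs <- sprintf("category_%02d", seq_len(n_categories))
  with_seed(seed, {
    first <- sample(labs, length(gene_ids), replace = TRUE)
    out <- data.frame(gene_id = gene_ids, category = first,
                      stringsAsFactors = FALSE)
    again <- stats::runif(length(gene_ids)) < multi_rate
    if (any(again)) {
      second <- sample(labs, sum(again), replace = TRUE)
      out <- rbind(out, data.frame(gene_id = gene_ids[again],
                                   category = second,
                                   stringsAsFactors = FALSE))
    }
    unique(out)
  })
}
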