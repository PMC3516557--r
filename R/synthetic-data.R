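# Synthetic-data generators. These emulate the statistical structure of
# the pipeline's real inputs — three linked gene universes with mixed
# orthology topology spread over several prediction sources, a screen hit
# list, sparse undirected binary interactions, gene-set collections with
# planted enrichment, and annotation sets with planted over-representation
# — so that every downstream stage can be exercised and calibrated without
# any external data.

#' Specification of a three-species synthetic gene universe
#'
#' Describes how many genes each species carries and which fraction of
#' the fly genes map to the mammalian species with each orthology
#' topology. Fractions that do not sum to one leave the remainder as
#' one-to-many mappings.
#'
#' @param n_fly,n_mouse,n_human Number of genes per species. The default
#'   fly universe of 14,000 approximates a genome-wide protein-coding
#'   RNAi screen; the mammalian universes are larger so that expanded
#'   (one-to-many / many-to-many) mappings always find unused targets.
#' @param frac_one_to_one Fraction of fly genes with exactly one ortholog
#'   in each mammalian species.
#' @param frac_many_to_many Fraction of fly genes participating in
#'   many-to-many ortholog groups (blocks of 2-3 fly genes fully
#'   connected to blocks of 2-3 targets).
#' @param frac_unmapped Fraction of fly genes with no mammalian ortholog.
#' @param seed Integer seed; identical seeds reproduce the universe
#'   byte for byte.
#' @return An object of class `universe_spec`.
#' @seealso [generate_universe()]
#' @export
universe_spec <- function(n_fly = 14000, n_mouse = 17000, n_human = 19000,
                          frac_one_to_one = 0.6, frac_many_to_many = 0.1,
                          frac_unmapped = 0.3, seed = 1L) {
  for (n in list(n_fly, n_mouse, n_human)) {
    if (!is_count(n)) stop_param("species sizes must be single non-negative integers")
  }
  for (f in list(frac_one_to_one, frac_many_to_many, frac_unmapped)) {
    if (!is_prob(f)) stop_param("fractions must be in [0, 1]")
  }
  if (frac_one_to_one + frac_many_to_many + frac_unmapped > 1 + 1e-12) {
    stop_param("topology fractions must sum to at most 1")
  }
  if (!is_count(seed)) stop_param("'seed' must be a single non-negative integer")
  structure(
    list(n_fly = as.integer(n_fly), n_mouse = as.integer(n_mouse),
         n_human = as.integer(n_human),
         frac_one_to_one = frac_one_to_one,
         frac_many_to_many = frac_many_to_many,
         frac_unmapped = frac_unmapped, seed = as.integer(seed)),
    class = "universe_spec"
  )
}

empty_ortholog_df <- function() {
  data.frame(source_species = character(0), source_id = character(0),
             target_species = character(0), target_id = character(0),
             method = character(0), stringsAsFactors = FALSE)
}

# Build the fly -> target mapping edge list for one target species.
# Category blocks (one-to-one / one-to-many / many-to-many) are assigned
# to the shuffled fly genes once by the caller; targets are consumed from
# a shuffled pool so no target is reused across mapping groups.
map_one_species <- function(cats, target_pool, target_species) {
  idx <- 0L
  take <- function(k) {
    if (idx + k > length(target_pool)) {
      stop_param("target universe for '%s' too small for requested topology",
                 target_species)
    }
    out <- target_pool[(idx + 1L):(idx + k)]
    idx <<- idx + k
    out
  }
  src <- character(0); tgt <- character(0)
  n11 <- length(cats$one_to_one)
  if (n11) {
    src <- c(src, cats$one_to_one)
    tgt <- c(tgt, take(n11))
  }
  if (length(cats$one_to_many)) {
    m <- sample(2:3, length(cats$one_to_many), replace = TRUE)
    src <- c(src, rep(cats$one_to_many, m))
    tgt <- c(tgt, take(sum(m)))
  }
  for (block in cats$many_to_many) {
    t_block <- take(sample(2:3, 1L))
    src <- c(src, rep(block, each = length(t_block)))
    tgt <- c(tgt, rep(t_block, length(block)))
  }
  data.frame(source_species = rep("fly", length(src)), source_id = src,
             target_species = rep(target_species, length(src)),
             target_id = tgt, stringsAsFactors = FALSE)
}

#' Generate a three-species gene universe with multi-source orthology
#'
#' Creates fly, mouse and human gene identifier lists and a set of
#' ortholog prediction tables (one per simulated source: `compara`,
#' `homologene`, `inparanoid`, `orthomcl`) whose union realizes the
#' mapping-topology fractions in `spec`. Every mapping is carried by at
#' least one source and independently by each further source with
#' probability 0.4, so the sources overlap but none is complete — as with
#' real pre-computed orthology predictions.
#'
#' @param spec A [universe_spec()].
#' @return A list of class `gene_universe` with elements `genes` (named
#'   list of fly/mouse/human ID vectors), `tables` (named list of
#'   per-source ortholog data frames), and `spec`.
#' @examples
#' u <- generate_universe(universe_spec(n_fly = 50, n_mouse = 120,
#'                                      n_human = 120, seed = 1))
#' lengths(u$genes)
#' @export
generate_universe <- function(spec) {
  if (!inherits(spec, "universe_spec")) stop_param("'spec' must be a universe_spec")
  genes <- list(
    fly = sprintf("CG%05d", seq_len(spec$n_fly)),
    mouse = sprintf("Mm%05d", seq_len(spec$n_mouse)),
    human = sprintf("Hs%05d", seq_len(spec$n_human))
  )
  sources <- c("compara", "homologene", "inparanoid", "orthomcl")
  if (spec$n_fly == 0L) {
    tables <- stats::setNames(rep(list(empty_ortholog_df()), length(sources)), sources)
    return(structure(list(genes = genes, tables = tables, spec = spec),
                     class = "gene_universe"))
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_fly
    n11 <- floor(spec$frac_one_to_one * n)
    nmm <- floor(spec$frac_many_to_many * n)
    nun <- floor(spec$frac_unmapped * n)
    n1m <- n - n11 - nmm - nun
    perm <- sample(genes$fly)
    cats <- list(
      one_to_one = perm[seq_len(n11)],
      many_to_many = split_blocks(perm[n11 + seq_len(nmm)]),
      one_to_many = perm[n11 + nmm + seq_len(n1m)],
      unmapped = perm[n11 + nmm + n1m + seq_len(nun)]
    )
    mapping <- rbind(
      map_one_species(cats, sample(genes$mouse), "mouse"),
      map_one_species(cats, sample(genes$human), "human")
    )
    nr <- nrow(mapping)
    tables <- stats::setNames(vector("list", length(sources)), sources)
    if (nr) {
      primary <- sample(seq_along(sources), nr, replace = TRUE)
      carry <- matrix(stats::runif(nr * length(sources)) < 0.4,
                      nrow = nr, ncol = length(sources))
      for (j in seq_along(sources)) {
        pick <- carry[, j] | primary == j
        tab <- mapping[pick, , drop = FALSE]
        tab$method <- rep(sources[j], nrow(tab))
        rownames(tab) <- NULL
        tables[[j]] <- tab[order(tab$source_id, tab$target_id, method = "radix"), ,
                           drop = FALSE]
        rownames(tables[[j]]) <- NULL
      }
    } else {
      tables <- stats::setNames(rep(list(empty_ortholog_df()), length(sources)), sources)
    }
    structure(list(genes = genes, tables = tables, spec = spec),
              class = "gene_universe")
  })
}

#' Draw a screen hit list and a developmental-lethal list
#'
#' Samples `n_hits` + `n_lethal` genes without replacement from one
#' species of the universe and splits them into two disjoint lists.
#'
#' @param universe A `gene_universe`.
#' @param n_hits Number of screen hits (default 580, the scale of a
#'   genome-wide thermal-nociception screen).
#' @param n_lethal Number of developmentally lethal genes.
#' @param seed Integer seed.
#' @param species Species to sample from (default `"fly"`).
#' @return List with character vectors `hits` and `lethals`.
#' @export
generate_screen <- function(universe, n_hits = 580, n_lethal = 100,
                            seed = 1L, species = "fly") {
  if (!is_count(n_hits) || !is_count(n_lethal)) {
    stop_param("'n_hits' and 'n_lethal' must be non-negative integers")
  }
  pool <- universe$genes[[species]]
  if (n_hits + n_lethal > length(pool)) {
    stop_param("n_hits + n_lethal (%d) exceeds the %s universe (%d)",
               n_hits + n_lethal, species, length(pool))
  }
  withr::with_seed(as.integer(seed), {
    drawn <- sample(pool, n_hits + n_lethal)
    list(hits = sort(drawn[seq_len(n_hits)], method = "radix"),
         lethals = sort(drawn[n_hits + seq_len(n_lethal)], method = "radix"))
  })
}

#' Generate a sparse undirected interaction network
#'
#' Edges follow an Erdos-Renyi G(n, p) model with
#' `p = mean_degree / (n - 1)`, so the expected edge count is
#' `n * mean_degree / 2`. Self-loops and duplicate edges cannot occur.
#'
#' @param universe A `gene_universe` (or a character vector of node IDs).
#' @param mean_degree Target mean degree (>= 0). The default of 1
#'   reflects the sparsity of curated yeast-two-hybrid binary
#'   interactomes, which report well under one partner per gene on
#'   average at genome scale.
#' @param seed Integer seed.
#' @param species Species whose genes become network nodes.
#' @return Data frame of undirected edges with columns `from`, `to`
#'   (each pair stored with `from < to`, rows sorted).
#' @export
generate_interactions <- function(universe, mean_degree = 1, seed = 1L,
                                  species = "fly") {
  nodes <- if (is.character(universe)) universe else universe$genes[[species]]
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L || mean_degree < 0) {
    stop_param("'mean_degree' must be a single non-negative number")
  }
  n <- length(nodes)
  if (n < 2L || mean_degree == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  p <- min(1, mean_degree / (n - 1))
  withr::with_seed(as.integer(seed), {
    g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    normalize_edges(data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                               stringsAsFactors = FALSE))
  })
}

#' Planted-effect parameters for gene-set and annotation generators
#'
#' @param n_sets Number of gene sets in a collection.
#' @param set_size_range Integer interval of set sizes, e.g. `c(30, 80)`
#'   (the scale of typical curated pathway collections).
#' @param n_planted Number of truly enriched ("planted") sets.
#' @param enrichment_factor Relative over-representation of screen hits in
#'   planted sets (>= 1; 1 means no planted effect).
#' @param annotation_base_rate Probability that a background gene carries
#'   an annotation (default 0.03, i.e. a few percent of the genome).
#' @param annotation_hit_rate Probability that a systems-map gene carries
#'   an annotation (default 0.38, the overlap scale seen for curated
#'   pain annotations).
#' @return An object of class `planted_effects`.
#' @export
planted_effects <- function(n_sets = 200, set_size_range = c(30, 80),
                            n_planted = 10, enrichment_factor = 5,
                            annotation_base_rate = 0.03,
                            annotation_hit_rate = 0.38) {
  if (!is_count(n_sets) || !is_count(n_planted)) {
    stop_param("'n_sets' and 'n_planted' must be non-negative integers")
  }
  if (n_planted > n_sets) stop_param("'n_planted' cannot exceed 'n_sets'")
  if (length(set_size_range) != 2L || any(set_size_range < 1) ||
      set_size_range[1] > set_size_range[2]) {
    stop_param("'set_size_range' must be an increasing positive interval")
  }
  if (!is.numeric(enrichment_factor) || enrichment_factor < 1) {
    stop_param("'enrichment_factor' must be >= 1")
  }
  if (!is_prob(annotation_base_rate) || !is_prob(annotation_hit_rate)) {
    stop_param("annotation rates must be in [0, 1]")
  }
  structure(
    list(n_sets = as.integer(n_sets),
         set_size_range = as.integer(set_size_range),
         n_planted = as.integer(n_planted),
         enrichment_factor = enrichment_factor,
         annotation_base_rate = annotation_base_rate,
         annotation_hit_rate = annotation_hit_rate),
    class = "planted_effects"
  )
}

#' Generate a gene-set collection with planted enrichment
#'
#' Non-planted sets are uniform samples (without replacement) from the
#' background. For a planted set of size s the number of hit members is
#' drawn `Binomial(s, min(1, factor * H / N))` (H = number of hits, N =
#' background size) and the members are then sampled uniformly without
#' replacement from hits and non-hits separately, so the expected hit
#' overlap of a planted set is exactly `s * factor * H / N` (up to the
#' cap at probability 1 and at H).
#'
#' @param background Character vector: the gene universe of the
#'   collection's species.
#' @param hits Character vector of screen hits (subset of `background`).
#' @param effects A [planted_effects()].
#' @param seed Integer seed.
#' @param prefix Set-name prefix.
#' @return List with `sets` (named list of member vectors) and `truth`
#'   (data frame `set_name`, `planted`, `enrichment_factor`).
#' @export
generate_genesets <- function(background, hits, effects = planted_effects(),
                              seed = 1L, prefix = "GS") {
  if (!inherits(effects, "planted_effects")) {
    stop_param("'effects' must be a planted_effects object")
  }
  N <- length(background)
  H <- length(hits)
  if (effects$n_sets > 0 && effects$set_size_range[2] > N) {
    stop_param("maximum set size (%d) exceeds background size (%d)",
               effects$set_size_range[2], N)
  }
  nonhits <- setdiff(background, hits)
  p_hit <- if (N > 0) min(1, effects$enrichment_factor * H / N) else 0
  withr::with_seed(as.integer(seed), {
    nm <- sprintf("%s%04d", prefix, seq_len(effects$n_sets))
    planted <- seq_len(effects$n_sets) <= effects$n_planted
    lo <- effects$set_size_range[1]; hi <- effects$set_size_range[2]
    sizes <- lo + sample.int(hi - lo + 1L, effects$n_sets, replace = TRUE) - 1L
    sets <- vector("list", effects$n_sets)
    for (i in seq_len(effects$n_sets)) {
      s <- sizes[i]
      if (planted[i]) {
        nh <- min(stats::rbinom(1L, s, p_hit), H, s)
        nn <- min(s - nh, length(nonhits))
        sets[[i]] <- sort(c(sample(hits, nh), sample(nonhits, nn)),
                          method = "radix")
      } else {
        sets[[i]] <- sort(sample(background, s), method = "radix")
      }
    }
    names(sets) <- nm
    truth <- data.frame(
      set_name = nm, planted = planted,
      enrichment_factor = ifelse(planted, effects$enrichment_factor, 1),
      stringsAsFactors = FALSE
    )
    list(sets = sets, truth = truth)
  })
}

#' Generate annotation gene sets with planted over-representation
#'
#' Each source annotates systems-map genes independently with probability
#' `annotation_hit_rate` and all other background genes with probability
#' `annotation_base_rate`, emulating curated disease annotations (OMIM-
#' style) and differential-expression call lists (microarray-style) that
#' are enriched among map genes.
#'
#' @param background Character vector: full gene universe.
#' @param map_genes Character vector of systems-map genes (subset of
#'   `background`).
#' @param effects A [planted_effects()] providing the two rates.
#' @param seed Integer seed.
#' @param sources Character vector of source labels.
#' @return Named list of sorted annotation gene vectors, one per source.
#' @export
generate_annotations <- function(background, map_genes,
                                 effects = planted_effects(), seed = 1L,
                                 sources = c("OMIM", "microarray")) {
  if (!inherits(effects, "planted_effects")) {
    stop_param("'effects' must be a planted_effects object")
  }
  map_genes <- intersect(map_genes, background)
  rest <- setdiff(background, map_genes)
  withr::with_seed(as.integer(seed), {
    out <- lapply(sources, function(src) {
      a <- map_genes[stats::runif(length(map_genes)) < effects$annotation_hit_rate]
      b <- rest[stats::runif(length(rest)) < effects$annotation_base_rate]
      sort(c(a, b), method = "radix")
    })
    stats::setNames(out, sources)
  })
}

#' Generate a random acyclic parent-child relation over set names
#'
#' Each set (after the first) gains a parent drawn from the earlier set
#' names with probability `p_child`, yielding a forest — a minimal
#' GO-style hierarchy for exercising ancestor-descendant pruning.
#'
#' @param set_names Character vector of term/set names.
#' @param seed Integer seed.
#' @param p_child Probability that a term has a parent.
#' @return Data frame with columns `child_id`, `parent_id`.
#' @export
generate_ontology <- function(set_names, seed = 1L, p_child = 0.5) {
  n <- length(set_names)
  if (n < 2L) {
    return(data.frame(child_id = character(0), parent_id = character(0),
                      stringsAsFactors = FALSE))
  }
  withr::with_seed(as.integer(seed), {
    has_parent <- stats::runif(n - 1L) < p_child
    child <- set_names[-1L][has_parent]
    parent <- vapply(which(has_parent) + 1L, function(i) {
      set_names[sample.int(i - 1L, 1L)]
    }, character(1))
    data.frame(child_id = child, parent_id = parent, stringsAsFactors = FALSE)
  })
}

#' Assign set names to functional classes at random
#'
#' Stands in for the manual grouping of significant pathways and gene
#' sets into functional classes; real runs supply a curated class map.
#'
#' @param set_names Character vector of set names.
#' @param n_classes Number of class labels.
#' @param seed Integer seed.
#' @return Data frame with columns `set_name`, `class_label`.
#' @export
generate_class_map <- function(set_names, n_classes = 8, seed = 1L) {
  if (!is_count(n_classes) || n_classes < 1) {
    stop_param("'n_classes' must be a positive integer")
  }
  if (length(set_names) == 0L) {
    return(data.frame(set_name = character(0), class_label = character(0),
                      stringsAsFactors = FALSE))
  }
  withr::with_seed(as.integer(seed), {
    labs <- sprintf("CLASS_%02d", seq_len(n_classes))
    data.frame(set_name = set_names,
               class_label = sample(labs, length(set_names), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
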