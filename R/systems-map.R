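# Assembly of the bipartite functional-class <-> gene systems map:
# significant sets from several species/collections are pooled into
# manually assigned functional classes, member genes are unified across
# species through the ortholog table (one node per gene, keyed by its
# fly anchor where one exists), and the resulting class-gene graph
# carries the node categories pain / binding_partner / lethal /
# functional_class. Two structural diagnostics mirror the network-level
# claims such a map must support: per-class hit representation and
# connectivity after removing all binding partners.

split_members <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(m) m[nzchar(m)])
}

# Map target-species gene IDs back to their fly anchor(s); IDs with no
# anchor are kept as-is (cannot normally occur for genes that were
# obtained by forward projection from fly). When `restrict` is given,
# anchors are limited to that gene universe (e.g. hits + partners +
# lethals) so that a many-to-many co-ortholog outside the screen never
# enters the map through the back door.
anchor_genes <- function(genes, species, ortholog_table, anchor_species,
                         restrict = NULL) {
  if (is.null(ortholog_table) || species == anchor_species) return(genes)
  sub <- ortholog_table[ortholog_table$target_species == species &
                          ortholog_table$source_species == anchor_species, ,
                        drop = FALSE]
  back <- split(sub$source_id, sub$target_id)
  unlist(lapply(genes, function(g) {
    a <- back[[g]]
    if (is.null(a)) return(g)
    if (!is.null(restrict)) {
      a2 <- intersect(a, restrict)
      if (length(a2)) a <- a2
    }
    sort_unique(a)
  }), use.names = FALSE)
}

#' Pool significant gene sets into functional classes
#'
#' Takes enrichment results from one or several species/collections,
#' keeps the significant sets, assigns each to its functional class via
#' the class map, and unions the sets' query-member genes into per-class
#' memberships. Member genes from different species are unified through
#' the ortholog table: a mammalian gene collapses onto its fly anchor(s)
#' where the table provides one. Significant sets absent from the class
#' map are excluded and reported as unassigned. The output is
#' independent of the order in which results are supplied.
#'
#' @param results One `enrichment_result` data frame or a list of them.
#'   An optional `species` column (or a `species` attribute per element)
#'   records provenance; missing species default to `"unspecified"`.
#' @param class_map Data frame (`set_name`, `class_label`).
#' @param ortholog_table Optional merged ortholog table used to unify
#'   genes across species.
#' @param anchor_species Species whose IDs key the unified gene nodes.
#' @param anchor_universe Optional character vector limiting which anchor
#'   genes may key a node (typically hits, partners and lethals); a
#'   mammalian gene whose anchors all fall outside keeps its own ID only
#'   if it has no anchors at all.
#' @return List of class `class_membership`: `membership` (data frame
#'   `class_label`, `gene_id`), `provenance` (data frame `class_label`,
#'   `set_name`, `species`, `collection`), `unassigned` (character).
#' @export
pool_into_classes <- function(results, class_map, ortholog_table = NULL,
                              anchor_species = "fly",
                              anchor_universe = NULL) {
  if (is.data.frame(results)) results <- list(results)
  tabs <- lapply(results, function(r) {
    sp <- attr(r, "species") %||% NULL
    r <- as.data.frame(r)
    if (!"species" %in% names(r)) {
      r$species <- rep(sp %||% "unspecified", nrow(r))
    }
    if (!"collection" %in% names(r)) r$collection <- rep(NA_character_, nrow(r))
    r[r$significant, c("set_name", "species", "collection", "member_hits"),
      drop = FALSE]
  })
  sig <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(sig) || nrow(sig) == 0L) {
    warning("no significant sets supplied; systems map will be empty")
    return(structure(list(
      membership = data.frame(class_label = character(0),
                              gene_id = character(0), stringsAsFactors = FALSE),
      provenance = data.frame(class_label = character(0),
                              set_name = character(0), species = character(0),
                              collection = character(0), stringsAsFactors = FALSE),
      unassigned = character(0)
    ), class = "class_membership"))
  }
  idx <- match(sig$set_name, class_map$set_name)
  unassigned <- sort_unique(sig$set_name[is.na(idx)])
  if (length(unassigned)) {
    warning(sprintf("%d significant set(s) missing from the class map; excluded",
                    length(unassigned)))
  }
  sig <- sig[!is.na(idx), , drop = FALSE]
  sig$class_label <- class_map$class_label[idx[!is.na(idx)]]
  members <- split_members(sig$member_hits)
  anchored <- lapply(seq_along(members), function(i) {
    anchor_genes(members[[i]], sig$species[i], ortholog_table, anchor_species,
                 restrict = anchor_universe)
  })
  membership <- unique(data.frame(
    class_label = rep(sig$class_label, lengths(anchored)),
    gene_id = unlist(anchored, use.names = FALSE),
    stringsAsFactors = FALSE
  ))
  membership <- membership[order(membership$class_label, membership$gene_id,
                                 method = "radix"), , drop = FALSE]
  rownames(membership) <- NULL
  provenance <- unique(sig[, c("class_label", "set_name", "species", "collection")])
  provenance <- provenance[order(provenance$class_label, provenance$set_name,
                                 provenance$species, method = "radix"), ,
                           drop = FALSE]
  rownames(provenance) <- NULL
  structure(list(membership = membership, provenance = provenance,
                 unassigned = unassigned),
            class = "class_membership")
}

category_colors <- c(functional_class = "gold", pain = "red",
                     binding_partner = "green", lethal = "blue")

#' Build the bipartite functional-class / gene systems map
#'
#' Class nodes connect to their member genes; gene nodes carry the
#' categories assigned by [categorize_nodes()]. The graph is bipartite
#' by construction and every node has degree >= 1. A member gene without
#' a category is an integrity error.
#'
#' @param membership A `class_membership` (or its `membership` data
#'   frame).
#' @param categories Data frame (`gene_id`, `category`).
#' @return An igraph object: vertex attributes `kind` (`"class"` /
#'   `"gene"`), `type` (logical, `TRUE` for classes — the bipartite
#'   partition), `category`, `color`.
#' @export
build_map <- function(membership, categories) {
  memb <- if (inherits(membership, "class_membership")) membership$membership else membership
  if (nrow(memb) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  classes <- sort_unique(memb$class_label)
  genes <- sort_unique(memb$gene_id)
  clash <- intersect(classes, genes)
  if (length(clash)) {
    stop_param("class labels collide with gene ids: %s",
               paste(utils::head(clash, 3L), collapse = ", "))
  }
  cat_idx <- match(genes, categories$gene_id)
  if (anyNA(cat_idx)) {
    stop_param("integrity error: no category for map gene(s): %s",
               paste(utils::head(genes[is.na(cat_idx)], 5L), collapse = ", "))
  }
  gene_cat <- categories$category[cat_idx]
  vertices <- data.frame(
    name = c(classes, genes),
    kind = c(rep("class", length(classes)), rep("gene", length(genes))),
    type = c(rep(TRUE, length(classes)), rep(FALSE, length(genes))),
    category = c(rep("functional_class", length(classes)), gene_cat),
    stringsAsFactors = FALSE
  )
  vertices$color <- unname(category_colors[vertices$category])
  g <- igraph::graph_from_data_frame(
    memb[, c("class_label", "gene_id")], directed = FALSE, vertices = vertices
  )
  message(sprintf("systems map: %d classes, %d genes, %d edges",
                  length(classes), length(genes), igraph::ecount(g)))
  g
}

#' Per-class representation of direct screen hits
#'
#' For each functional class, the fraction of its member genes
#' categorized `pain`. The convention is strict: a class at exactly 50
#' percent does NOT count as majority-hit.
#'
#' @param map An igraph systems map from [build_map()].
#' @return Data frame (`class_label`, `n_genes`, `n_pain`, `frac_pain`,
#'   `above_half`) with attribute `n_at_or_below_half`.
#' @export
class_hit_representation <- function(map) {
  kind <- igraph::vertex_attr(map, "kind")
  classes <- igraph::V(map)$name[kind == "class"]
  cat_of <- stats::setNames(igraph::vertex_attr(map, "category"),
                            igraph::V(map)$name)
  rows <- lapply(classes, function(cl) {
    members <- igraph::V(map)$name[as.integer(
      igraph::neighbors(map, cl))]
    n <- length(members)
    np <- sum(cat_of[members] == "pain")
    data.frame(class_label = cl, n_genes = n, n_pain = np,
               frac_pain = if (n > 0) np / n else NA_real_,
               above_half = n > 0 && np / n > 0.5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(class_label = character(0), n_genes = integer(0),
                      n_pain = integer(0), frac_pain = numeric(0),
                      above_half = logical(0), stringsAsFactors = FALSE)
  }
  attr(out, "n_at_or_below_half") <- sum(!out$above_half)
  out
}

#' Connectivity of the systems map with and without binding partners
#'
#' Counts connected components before and after deleting every
#' `binding_partner` gene node. The map's connectivity is "intact" when
#' the pruned map has no more components than the full map and no
#' functional-class node has been isolated by the removal.
#'
#' @param map An igraph systems map from [build_map()].
#' @return List: `components_full`, `components_pruned`,
#'   `isolated_classes` (character), `intact` (logical).
#' @export
connectivity_without_partners <- function(map) {
  full <- igraph::components(map)$no
  bp <- igraph::V(map)$name[igraph::vertex_attr(map, "category") == "binding_partner"]
  pruned <- igraph::delete_vertices(map, bp)
  kind <- igraph::vertex_attr(pruned, "kind")
  deg <- igraph::degree(pruned)
  isolated <- igraph::V(pruned)$name[kind == "class" & deg == 0]
  list(components_full = full,
       components_pruned = igraph::components(pruned)$no,
       isolated_classes = isolated,
       intact = igraph::components(pruned)$no <= full && length(isolated) == 0L)
}

#' Export a systems map as GraphML, SIF and a class-membership table
#'
#' Writes `<prefix>.graphml` (node attributes `kind`, `category`,
#' `color`), `<prefix>.sif` (`class  member  gene` triples) and
#' `<prefix>.membership.tsv`.
#'
#' @param map An igraph systems map.
#' @param prefix Output path prefix.
#' @param header Optional `#` header lines for the text formats.
#' @return Character vector of the written paths, invisibly.
#' @export
write_systems_map <- function(map, prefix, header = NULL) {
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(map, graphml, format = "graphml")
  el <- igraph::as_edgelist(map)
  kind <- stats::setNames(igraph::vertex_attr(map, "kind"), igraph::V(map)$name)
  # orient every SIF triple class -> gene
  swap <- kind[el[, 1]] != "class"
  el[swap, ] <- el[swap, c(2, 1)]
  sif <- paste0(prefix, ".sif")
  write_with_header(
    if (nrow(el)) paste(el[, 1], "member", el[, 2], sep = "\t") else character(0),
    sif, header
  )
  memb <- paste0(prefix, ".membership.tsv")
  df <- data.frame(class_label = el[, 1], gene_id = el[, 2],
                   category = igraph::vertex_attr(map, "category")[
                     match(el[, 2], igraph::V(map)$name)],
                   stringsAsFactors = FALSE)
  df <- df[order(df$class_label, df$gene_id, method = "radix"), , drop = FALSE]
  write_tsv(df, memb, header)
  invisible(c(graphml, sif, memb))
}
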