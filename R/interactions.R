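# Binary physical-interaction networks and first-degree neighborhood
# expansion. Interactions are undirected regardless of file order
# (physical binding is symmetric): every edge is normalized so that
# from < to, self-loops are dropped, duplicates collapse.

normalize_edges <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(df$from, df$to)
  b <- pmax(df$from, df$to)
  out <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a binary interaction table
#'
#' Reads a TSV with columns `source_id` and `target_id` (or `from`/`to`).
#' Self-loops are dropped with a warning; (A,B) and (B,A) collapse to one
#' undirected edge.
#'
#' @param path TSV file path.
#' @return Data frame of undirected edges (`from`, `to`; `from < to`).
#' @export
load_interactions <- function(path) {
  df <- read_tsv(path)
  cols <- if (all(c("source_id", "target_id") %in% names(df))) {
    c("source_id", "target_id")
  } else if (all(c("from", "to") %in% names(df))) {
    c("from", "to")
  } else {
    stop_param("format error in %s: need columns source_id/target_id", path)
  }
  edges <- data.frame(from = df[[cols[1]]], to = df[[cols[2]]],
                      stringsAsFactors = FALSE)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sprintf("%s: dropped %d self-loop(s)", path, sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  normalize_edges(edges)
}

#' Write an interaction edge list to TSV
#'
#' @param edges Edge data frame (`from`, `to`).
#' @param path Output path.
#' @param header Optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_interactions <- function(edges, path, header = NULL) {
  df <- data.frame(source_id = edges$from, target_id = edges$to,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}

#' First-degree binding partners of a hit set
#'
#' All network neighbors of hit genes that are not themselves hits:
#' `N(hits) \ hits`. Genes two or more steps away are never included.
#'
#' @param hits Character vector of hit gene IDs.
#' @param edges Undirected edge data frame (`from`, `to`).
#' @return Sorted character vector of partner gene IDs.
#' @export
first_degree_partners <- function(hits, edges) {
  nb <- c(edges$to[edges$from %in% hits], edges$from[edges$to %in% hits])
  sort_unique(setdiff(nb, hits))
}

#' Restrict a network to edges touching the hit set
#'
#' @param hits Character vector of hit gene IDs.
#' @param edges Undirected edge data frame.
#' @return List with `edges` (edges incident to >= 1 hit) and `partners`
#'   (the first-degree partners they introduce).
#' @export
hit_subnetwork <- function(hits, edges) {
  keep <- edges$from %in% hits | edges$to %in% hits
  sub <- edges[keep, , drop = FALSE]
  rownames(sub) <- NULL
  list(edges = sub, partners = first_degree_partners(hits, sub))
}

#' Categorize network nodes as pain hits, lethals or binding partners
#'
#' Every node receives exactly one category with precedence
#' `pain > lethal > binding_partner`: a screen hit is always `pain` even
#' if it also appears in the lethal list (an integrity warning is
#' emitted) or is a neighbor of another hit. Nodes that fall in none of
#' the three lists are an integrity error — the category assignment must
#' be total.
#'
#' @param hits Character vector of screen-hit gene IDs.
#' @param partners Character vector of first-degree partners (as computed
#'   by [first_degree_partners()]).
#' @param lethals Character vector of developmental-lethal gene IDs.
#' @param nodes Optional node set to categorize; defaults to the union of
#'   the three lists.
#' @return Data frame (`gene_id`, `category`) sorted by gene, with a
#'   `counts` attribute (named per-category totals).
#' @export
categorize_nodes <- function(hits, partners, lethals = character(0),
                             nodes = NULL) {
  hits <- unique(as.character(hits))
  partners <- unique(as.character(partners))
  lethals <- unique(as.character(lethals))
  if (is.null(nodes)) nodes <- c(hits, partners, lethals)
  nodes <- sort_unique(nodes)
  both <- intersect(hits, lethals)
  if (length(both)) {
    warning(sprintf("%d gene(s) are both screen hits and lethals; categorized 'pain': %s",
                    length(both), paste(utils::head(both, 5L), collapse = ", ")))
  }
  category <- ifelse(nodes %in% hits, "pain",
              ifelse(nodes %in% lethals, "lethal",
              ifelse(nodes %in% partners, "binding_partner", NA_character_)))
  if (anyNA(category)) {
    stop_param("integrity error: %d node(s) belong to no category (e.g. %s)",
               sum(is.na(category)), nodes[which(is.na(category))[1]])
  }
  out <- data.frame(gene_id = nodes, category = category,
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$category,
                         levels = c("pain", "binding_partner", "lethal")))
  attr(out, "counts") <- c(counts)
  message(sprintf("categorized %d nodes: %d pain, %d binding_partner, %d lethal",
                  nrow(out), counts[["pain"]], counts[["binding_partner"]],
                  counts[["lethal"]]))
  out
}

#' Write a categorized node table to TSV
#'
#' @param categories Data frame from [categorize_nodes()].
#' @param path Output path.
#' @param species Optional species label column value.
#' @param header Optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_node_categories <- function(categories, path, species = NA_character_,
                                  header = NULL) {
  df <- data.frame(gene_id = categories$gene_id,
                   species = rep(as.character(species), nrow(categories)),
                   category = categories$category,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}
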