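# Hypergeometric over-representation testing of a query gene set against
# gene-set collections, with collection-specific significance policies
# and GO-style ancestor-descendant pruning. Raw upper-tail probabilities
# are reported against fixed per-collection alphas; no multiple-testing
# correction is applied by default (a Benjamini-Hochberg column can be
# requested), matching the fixed-alpha convention of classical
# over-representation analyses.

#' Collection-specific significance policy
#'
#' Defaults: GO and KEGG sets are called significant at p < 0.1, C2 sets
#' at p < 0.01, and GO terms larger than 500 genes are excluded before
#' pruning (very broad terms are uninformative).
#'
#' @param go_alpha,kegg_alpha,c2_alpha Per-collection significance
#'   levels, each in (0, 1).
#' @param go_max_term_size Maximum GO term size retained.
#' @return An object of class `significance_policy`.
#' @export
significance_policy <- function(go_alpha = 0.1, kegg_alpha = 0.1,
                                c2_alpha = 0.01, go_max_term_size = 500) {
  for (a in list(go_alpha, kegg_alpha, c2_alpha)) {
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
      stop_param("alphas must be single numbers in (0, 1)")
    }
  }
  if (!is_count(go_max_term_size) || go_max_term_size < 1) {
    stop_param("'go_max_term_size' must be a positive integer")
  }
  structure(list(go_alpha = go_alpha, kegg_alpha = kegg_alpha,
                 c2_alpha = c2_alpha,
                 go_max_term_size = as.integer(go_max_term_size)),
            class = "significance_policy")
}

policy_alpha <- function(policy, collection) {
  switch(toupper(collection),
         GO = policy$go_alpha,
         KEGG = policy$kegg_alpha,
         C2 = policy$c2_alpha,
         stop_param("unknown collection label '%s' (use GO, KEGG or C2)",
                    collection))
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability of observing at least `k` annotated genes when drawing
#' `n` genes without replacement from a universe of `N` genes of which
#' `K` are annotated. Vectorized; numerically stable for N up to 1e6.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param n Query (draw) size.
#' @param K Gene-set size within the universe.
#' @param N Universe size.
#' @return Upper-tail probability in `[0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeometric_upper_tail(3, 5, 4, 10)  # 66/252
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  args <- cbind(k = k, n = n, K = K, N = N)
  if (any(is.na(args)) || any(args != floor(args)) || any(args < 0)) {
    stop_param("k, n, K, N must be non-negative integers")
  }
  if (any(args[, "K"] > args[, "N"]) || any(args[, "n"] > args[, "N"]) ||
      any(args[, "k"] > pmin(args[, "K"], args[, "n"]))) {
    stop_param("require k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of a query against a collection
#'
#' Every set is intersected with the background before testing; query
#' genes outside the background are dropped with a warning. One result
#' row per set, sorted by p-value then set name. `percent_mapped` is
#' `100 * k / K`, the share of the (background-restricted) set covered by
#' the query.
#'
#' @param query Character vector of query gene IDs.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe N.
#' @param policy A [significance_policy()].
#' @param collection_label One of `"GO"`, `"KEGG"`, `"C2"`; selects the
#'   alpha used for the significance flag.
#' @param adjust Also report Benjamini-Hochberg adjusted p-values in a
#'   `p_adjusted` column? (The flag `significant` always uses the raw p.)
#' @return Data frame of class `enrichment_result` with columns
#'   `set_name`, `collection`, `k`, `K`, `n`, `N`, `p_value`,
#'   `percent_mapped`, `significant`, `member_hits` (`;`-joined).
#' @export
enrich_collection <- function(query, collection, background,
                              policy = significance_policy(),
                              collection_label = "KEGG", adjust = FALSE) {
  background <- unique(as.character(background))
  N <- length(background)
  if (N == 0L) stop_param("background gene universe is empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the background universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  alpha <- policy_alpha(policy, collection_label)
  n <- length(query)
  in_query <- query
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), background)
    hits_in <- sort(members[members %in% in_query], method = "radix")
    K <- length(members)
    k <- length(hits_in)
    p <- hypergeometric_upper_tail(k, n, K, N)
    data.frame(set_name = nm, collection = collection_label,
               k = k, K = K, n = n, N = N, p_value = p,
               percent_mapped = if (K > 0) 100 * k / K else NA_real_,
               significant = p < alpha,
               member_hits = paste(hits_in, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(set_name = character(0), collection = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      percent_mapped = numeric(0), significant = logical(0),
                      member_hits = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_value, out$set_name, method = "radix"), , drop = FALSE]
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

# Transitive ancestor sets for the given terms under the parent-child
# relation (edges child -> parent). Errors on cycles.
ontology_ancestors <- function(terms, parent_child) {
  if (nrow(parent_child) == 0L) {
    return(stats::setNames(rep(list(character(0)), length(terms)), terms))
  }
  g <- igraph::graph_from_data_frame(
    parent_child[, c("child_id", "parent_id")], directed = TRUE
  )
  if (!igraph::is_dag(g)) {
    stop_param("format error: parent-child relation contains a cycle")
  }
  known <- igraph::V(g)$name
  stats::setNames(lapply(terms, function(t) {
    if (!t %in% known) return(character(0))
    anc <- igraph::subcomponent(g, t, mode = "out")$name
    setdiff(anc, t)
  }), terms)
}

#' Prune GO-style enrichment results along ancestor-descendant chains
#'
#' Two-step pruning of an enrichment table: (1) terms larger than
#' `policy$go_max_term_size` are removed regardless of p-value; (2) when
#' several significant terms lie on one ancestor-descendant chain of the
#' (transitively closed) parent-child relation, only the term with the
#' largest query overlap `k` is retained — ties broken by smaller
#' p-value, then lexicographic name. Non-significant terms pass through
#' untouched (beyond the size filter). Every removal is logged with its
#' reason.
#'
#' @param results An `enrichment_result` data frame.
#' @param parent_child Data frame (`child_id`, `parent_id`); must be
#'   acyclic.
#' @param policy A [significance_policy()].
#' @return List with `results` (pruned table) and `log` (data frame
#'   `set_name`, `reason`, `detail`).
#' @export
prune_go_results <- function(results, parent_child,
                             policy = significance_policy()) {
  log <- data.frame(set_name = character(0), reason = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  too_big <- results$K > policy$go_max_term_size
  if (any(too_big)) {
    log <- rbind(log, data.frame(
      set_name = results$set_name[too_big], reason = "term_size",
      detail = sprintf("K=%d > %d", results$K[too_big],
                       policy$go_max_term_size),
      stringsAsFactors = FALSE
    ))
    results <- results[!too_big, , drop = FALSE]
  }
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) > 1L && nrow(parent_child) > 0L) {
    anc <- ontology_ancestors(sig$set_name, parent_child)
    related <- function(a, b) b %in% anc[[a]] || a %in% anc[[b]]
    ord <- order(-sig$k, sig$p_value, sig$set_name, method = "radix")
    kept <- character(0)
    dropped <- character(0)
    winner <- character(0)
    for (i in ord) {
      nm <- sig$set_name[i]
      rel <- kept[vapply(kept, related, logical(1), b = nm)]
      if (length(rel)) {
        dropped <- c(dropped, nm)
        winner <- c(winner, rel[1])
      } else {
        kept <- c(kept, nm)
      }
    }
    if (length(dropped)) {
      log <- rbind(log, data.frame(
        set_name = dropped, reason = "hierarchy",
        detail = sprintf("superseded by %s (max-overlap rule)", winner),
        stringsAsFactors = FALSE
      ))
      results <- results[!results$set_name %in% dropped, , drop = FALSE]
    }
  }
  rownames(results) <- NULL
  list(results = results, log = log)
}

#' Write an enrichment table to TSV
#'
#' Columns mirror a classical pathway-enrichment report: set name, mapped
#' gene IDs, set size, overlap, percent of set mapped, hypergeometric p,
#' significance flag.
#'
#' @param results An `enrichment_result` data frame.
#' @param path Output path.
#' @param header Optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(results, path, header = NULL) {
  df <- as.data.frame(results)
  df$percent_mapped <- ifelse(is.na(df$percent_mapped), "NA",
                              sprintf("%.2f", df$percent_mapped))
  df$p_value <- sprintf("%.6g", df$p_value)
  write_tsv(df, path, header)
}
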