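# Fixture builders shared across the suite. Everything is constructed in
# code at test time; no binary or downloaded data.

# One ortholog record per element; vectors recycle (zero-length in,
# zero-row table out).
odf <- function(source_id, target_id, target_species = "human",
                method = "compara", source_species = "fly") {
  n <- max(length(source_id), length(target_id))
  data.frame(source_species = rep_len(source_species, n),
             source_id = rep_len(source_id, n),
             target_species = rep_len(target_species, n),
             target_id = rep_len(target_id, n),
             method = rep_len(method, n), stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  painmap::write_tsv(df, path)
  path
}

# Independent oracle: walk ortholog TSVs with nothing but readLines and
# strsplit, and count source genes with >= 1 target in the requested
# species. Shares no code with load_ortholog_table()/map_genes().
walk_count_mapped <- function(paths, queries, target_species) {
  mapped <- character(0)
  for (p in paths) {
    lines <- readLines(p)
    lines <- lines[!startsWith(lines, "#")]
    cols <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    src <- vapply(fields, `[[`, "", which(cols == "source_id"))
    tsp <- vapply(fields, `[[`, "", which(cols == "target_species"))
    mapped <- c(mapped, src[tsp == target_species & src %in% queries])
  }
  length(unique(mapped))
}

# A map at the scale of the published network figure: 20 functional
# classes over 244 genes (166 pain, 78 binding partners), plus optional
# lethals. `low_classes` names the classes deliberately built with <= 50%
# pain membership; every class keeps >= 1 pain gene unless listed in
# `partner_only`.
fig1_scale_fixture <- function(n_lethal = 0, partner_only = character(0)) {
  pain <- sprintf("CGP%03d", 1:166)
  bp <- sprintf("CGB%03d", 1:78)
  lethal <- if (n_lethal > 0) sprintf("CGL%03d", seq_len(n_lethal)) else character(0)
  classes <- sprintf("CLASS_%02d", 1:20)
  # classes 1..17: majority pain (8 pain + 3 bp); 18,19: exactly half
  # (4 + 4); 20: below half (3 pain + 6 bp). Genes recycle across classes.
  comp <- list()
  pi <- 1; bi <- 1
  take <- function(pool, i, k) pool[((i - 1 + seq_len(k)) %% length(pool)) + 1]
  for (j in 1:20) {
    if (j <= 17) { np <- 8; nb <- 3 } else if (j <= 19) { np <- 4; nb <- 4 }
    else { np <- 3; nb <- 6 }
    comp[[classes[j]]] <- c(take(pain, pi, np), take(bp, bi, nb))
    pi <- pi + np; bi <- bi + nb
  }
  # ensure every pain/bp gene appears in at least one class
  leftover_p <- setdiff(pain, unlist(comp))
  leftover_b <- setdiff(bp, unlist(comp))
  # park all leftovers in CLASS_01, keeping it majority-pain
  comp[["CLASS_01"]] <- unique(c(comp[["CLASS_01"]], leftover_p, leftover_b))
  for (cl in partner_only) comp[[cl]] <- take(bp, 1, 5)
  if (n_lethal > 0) comp[["CLASS_03"]] <- c(comp[["CLASS_03"]], lethal)
  membership <- data.frame(
    class_label = rep(names(comp), lengths(comp)),
    gene_id = unlist(comp, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  categories <- suppressMessages(categorize_nodes(pain, bp, lethal))
  low_classes <- c("CLASS_18", "CLASS_19", "CLASS_20", partner_only)
  list(membership = unique(membership), categories = categories,
       pain = pain, bp = bp, lethal = lethal,
       low_classes = sort(unique(low_classes)))
}

# Build gene lists realizing given per-category annotation-overlap
# counts, so the report arithmetic can be checked against printed-table
# values: the counts are the input, the percentages the output.
make_overlap_fixture <- function(pain_total = 166, pain_a = 40, pain_b = 34,
                                 pain_both = 10, bp_total = 78, bp_a = 20,
                                 bp_b = 23, bp_both = 10) {
  pain <- sprintf("P%03d", seq_len(pain_total))
  bp <- sprintf("B%03d", seq_len(bp_total))
  pick <- function(genes, n_a, n_b, n_both) {
    a <- genes[seq_len(n_a)]
    b <- c(genes[seq_len(n_both)], genes[n_a + seq_len(n_b - n_both)])
    list(a = a, b = b)
  }
  p <- pick(pain, pain_a, pain_b, pain_both)
  q <- pick(bp, bp_a, bp_b, bp_both)
  list(
    categories = data.frame(
      gene_id = c(pain, bp),
      category = rep(c("pain", "binding_partner"), c(pain_total, bp_total)),
      stringsAsFactors = FALSE),
    annot_a = c(p$a, q$a), annot_b = c(p$b, q$b)
  )
}

# Exhaustive combinatorial oracle for the hypergeometric upper tail,
# independent of stats::phyper: log-space sum of C(K,j) C(N-K,n-j) / C(N,n).
enum_upper_tail <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  if (length(j) == 0) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
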