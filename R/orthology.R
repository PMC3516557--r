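# Multi-source ortholog tables and cross-species projection of gene
# lists. Tables are plain data frames with one row per
# (source gene, target gene, prediction method) triple; merging pools
# sources by set union and projection de-duplicates target genes, so
# one-to-many and many-to-many mappings expand naturally.

ortholog_cols <- c("source_species", "source_id", "target_species",
                   "target_id", "method")

validate_ortholog_table <- function(df) {
  missing <- setdiff(ortholog_cols, names(df))
  if (length(missing)) {
    stop_param("ortholog table missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  df[, ortholog_cols, drop = FALSE]
}

#' Load one ortholog prediction table from TSV
#'
#' Expected columns: `source_species`, `source_id`, `target_species`,
#' `target_id` and (unless `method_label` is given) `method`. Malformed
#' rows (empty required fields) are dropped with a warning naming their
#' data-row numbers; duplicated (source, target, method) triples are
#' collapsed with a warning.
#'
#' @param path TSV file path.
#' @param method_label Optional method label applied to every row,
#'   overriding / standing in for a `method` column.
#' @return Ortholog table data frame.
#' @export
load_ortholog_table <- function(path, method_label = NULL) {
  need <- c("source_species", "source_id", "target_species", "target_id")
  df <- read_tsv(path, required = need)
  if (!is.null(method_label)) {
    df$method <- rep(as.character(method_label), nrow(df))
  } else if (!"method" %in% names(df)) {
    stop_param("format error in %s: no 'method' column and no method_label given", path)
  }
  df <- df[, ortholog_cols, drop = FALSE]
  ok <- Reduce(`&`, lapply(df[need], function(x) !is.na(x) & nzchar(trimws(x))))
  if (nrow(df) && any(!ok)) {
    warning(sprintf("%s: dropping malformed row(s) at data line(s) %s",
                    path, paste(which(!ok), collapse = ", ")))
    df <- df[ok, , drop = FALSE]
  }
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("%s: removed %d duplicated mapping row(s)", path, sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Merge ortholog tables from several prediction sources
#'
#' Takes the set union of all (source, target, method) records. The
#' provenance of one mapping is the set of method labels that carry it;
#' see [ortholog_provenance()] for the aggregated per-mapping view.
#' A gene identifier attached to two different species labels anywhere in
#' the input is an integrity error, since (species, id) is the unique
#' gene key throughout the pipeline.
#'
#' @param tables A list of ortholog table data frames (or a single one).
#' @return One merged ortholog table, rows sorted, no duplicate triples.
#' @export
merge_tables <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 1L) stop_param("need at least one table")
  tables <- lapply(tables, validate_ortholog_table)
  df <- unique(do.call(rbind, tables))
  pairs <- unique(rbind(
    data.frame(species = df$source_species, id = df$source_id,
               stringsAsFactors = FALSE),
    data.frame(species = df$target_species, id = df$target_id,
               stringsAsFactors = FALSE)
  ))
  clash <- unique(pairs$id[duplicated(pairs$id)])
  if (length(clash)) {
    stop_param("integrity error: gene id(s) attached to more than one species: %s",
               paste(utils::head(clash, 5L), collapse = ", "))
  }
  df <- df[do.call(order, c(unname(as.list(df)), list(method = "radix"))), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-mapping provenance of a merged ortholog table
#'
#' @param table An ortholog table data frame.
#' @return Data frame with one row per distinct (source, target) mapping
#'   and a `methods` column holding the sorted, `;`-joined contributing
#'   method labels.
#' @export
ortholog_provenance <- function(table) {
  table <- validate_ortholog_table(table)
  key <- paste(table$source_species, table$source_id,
               table$target_species, table$target_id, sep = "\r")
  methods <- vapply(split(table$method, key), function(m) {
    paste(sort_unique(m), collapse = ";")
  }, character(1))
  first <- table[!duplicated(key), c("source_species", "source_id",
                                     "target_species", "target_id")]
  first$methods <- methods[paste(first$source_species, first$source_id,
                                 first$target_species, first$target_id,
                                 sep = "\r")]
  first <- first[order(first$source_id, first$target_species,
                       first$target_id, method = "radix"), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Project a gene list into a target species through an ortholog table
#'
#' Returns the de-duplicated union of all target-species orthologs of the
#' query genes (many-to-many mappings expand), plus a per-query report.
#' A target species absent from the table yields an empty result with a
#' warning, not an error.
#'
#' @param genes Character vector of query gene IDs (one species).
#' @param table An ortholog table data frame (typically merged).
#' @param target_species Target species label, e.g. `"human"`.
#' @param source_species Optional source species label; defaults to any.
#' @return A list of class `ortholog_mapping`: `targets` (sorted unique
#'   target IDs), `report` (data frame `query_id`, `n_targets`,
#'   `target_ids` semicolon-joined), `n_mapped` (queries with >= 1
#'   target), `target_species`.
#' @export
map_genes <- function(genes, table, target_species, source_species = NULL) {
  table <- validate_ortholog_table(table)
  genes <- unique(as.character(genes))
  sub <- table[table$target_species == target_species, , drop = FALSE]
  if (!is.null(source_species)) {
    sub <- sub[sub$source_species == source_species, , drop = FALSE]
  }
  if (nrow(sub) == 0L && length(genes) &&
      !target_species %in% table$target_species) {
    warning(sprintf("target species '%s' not present in ortholog table",
                    target_species))
  }
  sub <- sub[sub$source_id %in% genes, , drop = FALSE]
  by_query <- split(sub$target_id, sub$source_id)
  tg <- lapply(genes, function(g) sort_unique(by_query[[g]] %||% character(0)))
  report <- data.frame(
    query_id = genes,
    n_targets = lengths(tg),
    target_ids = vapply(tg, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  report <- report[order(report$query_id, method = "radix"), , drop = FALSE]
  rownames(report) <- NULL
  structure(
    list(targets = sort_unique(sub$target_id),
         report = report,
         n_mapped = sum(report$n_targets > 0L),
         target_species = target_species),
    class = "ortholog_mapping"
  )
}

#' @export
print.ortholog_mapping <- function(x, ...) {
  cat(sprintf("ortholog projection to %s: %d/%d query genes mapped, %d distinct targets\n",
              x$target_species, x$n_mapped, nrow(x$report), length(x$targets)))
  invisible(x)
}

#' Write an ortholog mapping report to TSV
#'
#' @param mapping An `ortholog_mapping`.
#' @param path Output path.
#' @param header Optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_mapping_report <- function(mapping, path, header = NULL) {
  write_tsv(mapping$report, path, header)
}
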