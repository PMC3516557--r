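# Readers and writers for the pipeline's plain-text formats: gene lists
# (one ID per line), TSV tables, GMT gene-set collections, annotation
# tables, ontology parent-child relations and class maps. All writers can
# prepend '#'-prefixed provenance headers (tool version, seed, config
# hash); all readers skip '#' lines.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  h <- sprintf("# painmap %s", as.character(utils::packageVersion("painmap")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config_hash)) h <- c(h, sprintf("# config=%s", config_hash))
  h
}

write_with_header <- function(lines, path, header = NULL) {
  con <- file(path, open = "wb")  # binary mode: LF endings everywhere
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

df_to_tsv_lines <- function(df) {
  if (nrow(df) == 0L) return(paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  c(paste(names(df), collapse = "\t"), body)
}

#' Write a tab-separated table with an optional provenance header
#'
#' @param df A data frame.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines
#'   (see `provenance_header`); `NULL` writes none.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path, header = NULL) {
  write_with_header(df_to_tsv_lines(df), path, header)
}

#' Read a tab-separated table, skipping '#' comment lines
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return A data frame of character columns.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_param("format error in %s: missing column(s) %s",
               path, paste(missing, collapse = ", "))
  }
  df
}

#' Read and write plain gene lists (one identifier per line)
#'
#' Comment (`#`) and empty lines are skipped on read; order is preserved
#' and duplicates are kept (callers decide whether to de-duplicate).
#'
#' @param path File path.
#' @param genes Character vector of gene identifiers.
#' @param header Optional `#` header lines for the writer.
#' @return `read_gene_list`: a character vector. `write_gene_list`: the
#'   path, invisibly.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path, header = NULL) {
  write_with_header(as.character(genes), path, header)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Lines starting with `#` are skipped on read.
#'
#' @param path File path.
#' @param sets Named list of character vectors (set members).
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled; defaults to `"na"`).
#' @param header Optional `#` header lines for the writer.
#' @return `read_gmt`: a named list of character vectors with a
#'   `"descriptions"` attribute. `write_gmt`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    warning(sprintf("dropping %d GMT line(s) with fewer than 3 fields", length(bad)))
    fields <- fields[lengths(fields) >= 3L]
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL, header = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  write_with_header(lines, path, header)
}

#' Read an annotation table into per-source gene sets
#'
#' The table has columns `gene_id` and `source_label` (e.g. `OMIM`,
#' `microarray_DH`, `microarray_DRG`). By default all `microarray_*`
#' labels are unioned into one `microarray` set, mirroring a combined
#' microarray evidence column; set `union_microarray = FALSE` to keep
#' them separate.
#'
#' @param path File path.
#' @param union_microarray Pool `microarray_*` labels into one set?
#' @return Named list of character gene-ID vectors, one per source.
#' @export
read_annotations <- function(path, union_microarray = TRUE) {
  df <- read_tsv(path, required = c("gene_id", "source_label"))
  sets <- lapply(split(df$gene_id, df$source_label), sort_unique)
  if (union_microarray) {
    ma <- grepl("^microarray", names(sets))
    if (any(ma)) {
      pooled <- sort_unique(unlist(sets[ma], use.names = FALSE))
      sets <- c(sets[!ma], list(microarray = pooled))
    }
  }
  sets
}

#' @rdname read_annotations
#' @param annotations Named list of character vectors (gene sets).
#' @param header Optional `#` header lines.
#' @export
write_annotations <- function(annotations, path, header = NULL) {
  df <- data.frame(
    gene_id = unlist(annotations, use.names = FALSE),
    source_label = rep(names(annotations), lengths(annotations)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$source_label, df$gene_id, method = "radix"), , drop = FALSE]
  write_tsv(df, path, header)
}

#' Read an ontology parent-child relation table
#'
#' @param path TSV with columns `child_id`, `parent_id`.
#' @return Data frame with columns `child_id`, `parent_id`.
#' @export
read_parent_child <- function(path) {
  read_tsv(path, required = c("child_id", "parent_id"))[, c("child_id", "parent_id")]
}

#' Read a functional-class assignment table
#'
#' @param path TSV with columns `set_name`, `class_label`.
#' @return Data frame with columns `set_name`, `class_label`.
#' @export
read_class_map <- function(path) {
  unique(read_tsv(path, required = c("set_name", "class_label"))[, c("set_name", "class_label")])
}
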