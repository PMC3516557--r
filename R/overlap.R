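# Overlap validation of the systems map against known pain annotations:
# a per-category report (counts and half-up two-decimal percentages of
# map genes matching an OMIM-style and a microarray-style annotation set,
# with the union by inclusion-exclusion) and a size-matched
# random-gene-list null for the union overlap.

#' Percentage with half-up rounding to two decimals
#'
#' `100 * count / total` rounded half-up (0.005 rounds away from zero) to
#' two decimals — the convention that reproduces e.g. 40/166 = 24.10 and
#' 33/78 = 42.31. A zero total is undefined and returns `NA`.
#'
#' @param count,total Non-negative integers with `count <= total`.
#' @return Numeric percentage (two decimals) or `NA_real_`.
#' @examples
#' percent(64, 166)  # 38.55
#' @export
percent <- function(count, total) {
  if (any(count < 0) || any(total < 0) || any(count > total)) {
    stop_param("require 0 <= count <= total")
  }
  out <- ifelse(total == 0, NA_real_, floor(100 * count / total * 100 + 0.5) / 100)
  unname(out)
}

# Shared overlap arithmetic: both the observed report and the random-list
# null go through this single code path.
overlap_counts <- function(genes, annot_a, annot_b) {
  a <- sum(genes %in% annot_a)
  b <- sum(genes %in% annot_b)
  both <- sum(genes %in% annot_a & genes %in% annot_b)
  c(a = a, b = b, both = both, union = a + b - both)
}

#' Overlap of systems-map genes with two annotation sources
#'
#' One row per gene category (by default `pain` and `binding_partner`):
#' category size and its share of the map, counts and percentages
#' matching source A (OMIM-style) and source B (microarray-style), the
#' count matching both, and the union by inclusion-exclusion. All
#' percentages use half-up two-decimal rounding via [percent()].
#'
#' @param categories Data frame (`gene_id`, `category`) of map genes.
#' @param annot_a,annot_b Character vectors of annotated gene IDs in the
#'   same namespace as the map genes.
#' @param category_levels Categories to report, in order.
#' @return Data frame of class `overlap_report` with columns `category`,
#'   `total`, `share_pct`, `a_count`, `a_pct`, `b_count`, `b_pct`,
#'   `both_count`, `union_count`, `union_pct`.
#' @export
overlap_report <- function(categories, annot_a, annot_b,
                           category_levels = c("pain", "binding_partner")) {
  annot_a <- unique(as.character(annot_a))
  annot_b <- unique(as.character(annot_b))
  by_cat <- split(categories$gene_id, categories$category)
  total_map <- sum(categories$category %in% category_levels)
  rows <- lapply(category_levels, function(cl) {
    genes <- unique(by_cat[[cl]] %||% character(0))
    n <- length(genes)
    cts <- overlap_counts(genes, annot_a, annot_b)
    data.frame(category = cl, total = n,
               share_pct = percent(n, total_map),
               a_count = cts[["a"]], a_pct = percent(cts[["a"]], n),
               b_count = cts[["b"]], b_pct = percent(cts[["b"]], n),
               both_count = cts[["both"]],
               union_count = cts[["union"]],
               union_pct = percent(cts[["union"]], n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of systems-map genes with annotation sources A and B\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Random-gene-list null for the union annotation overlap
#'
#' Draws `R` gene lists of size `list_size` uniformly without replacement
#' from the background and computes each list's union-overlap percentage
#' with the two annotation sources exactly as [overlap_report()] does.
#' If an observed percentage is supplied, the empirical p-value is
#' `(1 + #\{null >= observed\}) / (R + 1)`.
#'
#' @param background Character vector to sample from.
#' @param list_size Size of each random list (match the size of the map
#'   category under test).
#' @param annot_a,annot_b Annotation gene-ID vectors.
#' @param R Number of random lists (default 100).
#' @param seed Integer seed (recorded in the result for audit).
#' @param observed Optional observed union-overlap percentage.
#' @return Object of class `null_summary`: `percents` (length R), `max`,
#'   `min`, `mean`, `R`, `list_size`, `seed`, `observed`, `p_empirical`.
#' @export
random_list_null <- function(background, list_size, annot_a, annot_b,
                             R = 100, seed = 1L, observed = NULL) {
  background <- unique(as.character(background))
  if (!is_count(list_size) || list_size < 1) {
    stop_param("'list_size' must be a positive integer")
  }
  if (list_size > length(background)) {
    stop_param("list_size (%d) exceeds background size (%d)",
               list_size, length(background))
  }
  if (!is_count(R) || R < 1) stop_param("'R' must be a positive integer")
  annot_a <- unique(as.character(annot_a))
  annot_b <- unique(as.character(annot_b))
  percents <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(R), function(i) {
      g <- sample(background, list_size)
      percent(overlap_counts(g, annot_a, annot_b)[["union"]], list_size)
    }, numeric(1))
  })
  p_emp <- if (!is.null(observed)) {
    (1 + sum(percents >= observed)) / (R + 1)
  } else NA_real_
  structure(
    list(percents = percents, max = max(percents), min = min(percents),
         mean = mean(percents), R = as.integer(R),
         list_size = as.integer(list_size), seed = as.integer(seed),
         observed = observed, p_empirical = p_emp),
    class = "null_summary"
  )
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "random-list null: R=%d lists of %d genes; overlap %% min=%.2f mean=%.2f max=%.2f\n",
    x$R, x$list_size, x$min, x$mean, x$max))
  if (!is.null(x$observed)) {
    cat(sprintf("observed %.2f%% -> empirical p = %.4g\n", x$observed,
                x$p_empirical))
  }
  invisible(x)
}

#' Write an overlap report (TSV + JSON) and its null distribution (TSV)
#'
#' @param report An `overlap_report`.
#' @param nulls Optional named list of `null_summary` objects (one per
#'   category).
#' @param prefix Output path prefix.
#' @param header Optional `#` header lines.
#' @return Character vector of written paths, invisibly.
#' @export
write_overlap_report <- function(report, nulls = NULL, prefix,
                                 header = NULL) {
  paths <- paste0(prefix, ".overlap.tsv")
  write_tsv(as.data.frame(report), paths, header)
  json <- paste0(prefix, ".overlap.json")
  payload <- list(report = as.data.frame(report))
  if (!is.null(nulls)) {
    payload$null <- lapply(nulls, function(ns) {
      ns[c("R", "list_size", "seed", "min", "mean", "max", "observed",
           "p_empirical")]
    })
  }
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, json)
  if (!is.null(nulls)) {
    nd <- paste0(prefix, ".null.tsv")
    df <- do.call(rbind, c(lapply(names(nulls), function(nm) {
      data.frame(category = nm, replicate = seq_along(nulls[[nm]]$percents),
                 union_pct = nulls[[nm]]$percents, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    write_tsv(df, nd, header)
    paths <- c(paths, nd)
  }
  invisible(paths)
}
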