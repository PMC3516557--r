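# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radix sort gives a locale-independent (C-collation) order, so outputs are
# byte-identical across machines.
sort_unique <- function(x) sort(unique(x), method = "radix")

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Derive a per-stage child seed from one global seed
#'
#' One run-level seed fans out deterministically to the individual
#' generators and resampling stages, so any stage can be regenerated in
#' isolation and still match an end-to-end run. The derivation is
#' `(seed * 131 + offset(stage)) mod (2^31 - 1)` with a fixed per-stage
#' offset table; it is part of the package contract and will not change
#' between versions.
#'
#' @param seed Integer global seed (non-negative, below 2^31).
#' @param stage Character vector of stage names; one of `"universe"`,
#'   `"screen"`, `"interactions"`, `"genesets"`, `"annotations"`,
#'   `"ontology"`, `"class_map"`, `"null"`, `"query"`.
#' @return Integer vector of child seeds, one per requested stage.
#' @examples
#' derive_seed(7, c("universe", "screen"))
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(
    universe = 1L, screen = 2L, interactions = 3L, genesets = 4L,
    annotations = 5L, ontology = 6L, class_map = 7L, null = 8L,
    query = 9L
  )
  if (!is_count(seed)) stop_param("'seed' must be a single non-negative integer")
  bad <- setdiff(stage, names(offsets))
  if (length(bad)) stop_param("unknown stage name(s): %s", paste(bad, collapse = ", "))
  as.integer((as.numeric(seed) * 131 + offsets[stage]) %% 2147483647)
}

# Split a vector into consecutive blocks whose sizes are drawn from
# `sizes`; a trailing remainder of 1 is folded into the previous block so
# every block has >= 2 elements (needed for many-to-many topology).
split_blocks <- function(x, sizes = 2:3) {
  n <- length(x)
  if (n == 0L) return(list())
  take <- integer(0)
  while (sum(take) < n) take <- c(take, sample(sizes, 1L))
  over <- sum(take) - n
  take[length(take)] <- take[length(take)] - over
  if (take[length(take)] == 1L && length(take) > 1L) {
    take[length(take) - 1L] <- take[length(take) - 1L] + 1L
    take <- take[-length(take)]
  }
  split(x, rep(seq_along(take), take))
}
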