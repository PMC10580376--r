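#' Build a reference pool of unique receptors
#'
#' Generates `n` receptors from the engine, deduplicates them, and (when
#' `path` is given) persists the pool with pgen annotations so it can be
#' queried repeatedly without regeneration. This is the recommended way to
#' obtain signal-pool candidates without motif implantation: generate a
#' large reference set once, then select the sequences that naturally carry
#' patterns of interest with [match_patterns()].
#'
#' @param engine A generative engine.
#' @param n Number of receptors to draw before deduplication.
#' @param seed Integer seed.
#' @param path Optional TSV path (`junction_aa`, `v_call`, `j_call`, `pgen`)
#'   to persist the pool.
#' @return A receptor tibble of unique sequences with `pgen` set.
#' @export
build_reference_pool <- function(engine, n, seed, path = NULL) {
  stopifnot(n >= 1)
  pool <- engine_sample(engine, n, seed)
  pool <- pool[!duplicated(receptor_key(pool)), ]
  if (!is.null(path)) readr::write_tsv(pool, path)
  pool
}

#' Pattern query over a receptor pool
#'
#' @param patterns Character vector of contiguous amino-acid substrings
#'   (e.g. 4-mers).
#' @param match_mode `"any"` (a sequence matches if it contains at least one
#'   pattern, the default) or `"all"` (must contain every pattern).
#' @param v_call,j_call Optional gene constraints; a non-`NULL` value keeps
#'   only receptors whose call is in the given set.
#' @return An object of class `pattern_query`.
#' @export
#' @examples
#' pattern_query(c("WKDY", "YREV", "ERFY"))
pattern_query <- function(patterns, match_mode = c("any", "all"),
                          v_call = NULL, j_call = NULL) {
  match_mode <- match.arg(match_mode)
  if (length(patterns) == 0 || !all(is_valid_aa(patterns))) {
    abort("patterns must be non-empty amino-acid strings",
          class = "pubsim_validation_error")
  }
  structure(list(patterns = patterns, match_mode = match_mode,
                 v_call = v_call, j_call = j_call),
            class = "pattern_query")
}

#' Retrieve pool sequences matching a pattern query
#'
#' Plain substring containment anywhere in the junction (no positional
#' restriction and no modification of the sequences — matching selects
#' naturally occurring carriers rather than implanting motifs, which would
#' distort the biological properties of the sequences). Output order is the
#' pool order; overlapping hits within one sequence count once.
#'
#' @param pool A receptor tibble (non-empty).
#' @param query A [pattern_query()], or a character vector of patterns
#'   (treated as an any-of query).
#' @return The matching subset of `pool`, in pool order.
#' @export
match_patterns <- function(pool, query) {
  pool <- validate_receptors(pool)
  if (nrow(pool) == 0) {
    abort("pool is empty", class = "pubsim_validation_error")
  }
  if (is.character(query)) query <- pattern_query(query)
  stopifnot(inherits(query, "pattern_query"))
  hits <- vapply(query$patterns, function(p) {
    stringr::str_detect(pool$junction_aa, stringr::fixed(p))
  }, logical(nrow(pool)))
  hits <- matrix(hits, nrow = nrow(pool))
  keep <- if (query$match_mode == "any") {
    rowSums(hits) > 0
  } else {
    rowSums(hits) == length(query$patterns)
  }
  if (!is.null(query$v_call)) keep <- keep & pool$v_call %in% query$v_call
  if (!is.null(query$j_call)) keep <- keep & pool$j_call %in% query$j_call
  pool[keep, ]
}
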