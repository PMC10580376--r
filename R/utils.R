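# Shared small helpers: amino-acid alphabet, rounding, seed derivation.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_valid_aa <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
}

# round half up (base round() rounds half to even, which is not what the
# incidence-count conversion wants: 2.5 repertoires -> 3)
round_half_up <- function(x) floor(x + 0.5)

#' Derive a reproducible stage seed from a top-level seed
#'
#' All randomness in a simulation flows from a single top-level seed; each
#' workflow stage re-seeds from a label-specific derivation so that stages can
#' be rerun independently yet reproducibly. The derived seed always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Integer top-level seed.
#' @param label Character stage label (e.g. `"baseline"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, "baseline")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  h <- as.double(seed %% m)
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}

# evaluate `code` under a derived seed without disturbing the caller's RNG
with_stage_seed <- function(seed, label, code) {
  withr::with_seed(derive_seed(seed, label), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
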