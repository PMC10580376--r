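#' Build and validate a receptor table
#'
#' A receptor is identified by the triple (junction_aa, v_call, j_call): two
#' receptors are the same sequence if and only if all three fields match.
#' Receptor tables are plain tibbles with those three character columns plus
#' an optional `pgen` column (the V(D)J generation probability, in `[0, 1]`,
#' or `NA` when not yet computed).
#'
#' @param junction_aa Amino-acid junction strings (20-letter alphabet).
#' @param v_call,j_call V/J gene identifier strings.
#' @param pgen Optional generation probabilities in `[0, 1]`; `NA` permitted.
#' @return A tibble with columns `junction_aa`, `v_call`, `j_call`, `pgen`.
#' @export
#' @examples
#' receptor_tbl("CASSLGETQYF", "TRBV1", "TRBJ2-5", pgen = 1e-7)
receptor_tbl <- function(junction_aa, v_call, j_call, pgen = NA_real_) {
  out <- tibble(
    junction_aa = as.character(junction_aa),
    v_call = as.character(v_call),
    j_call = as.character(j_call),
    pgen = as.double(pgen)
  )
  validate_receptors(out)
}

#' @rdname receptor_tbl
#' @param x A data frame to validate as a receptor table.
#' @export
validate_receptors <- function(x) {
  x <- as_tibble(x)
  required <- c("junction_aa", "v_call", "j_call")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("receptor table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pubsim_schema_error")
  }
  bad <- which(!is_valid_aa(x$junction_aa))
  if (length(bad) > 0) {
    abort(paste0("invalid amino-acid junction at row(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""),
          class = "pubsim_schema_error")
  }
  if (!"pgen" %in% names(x)) x$pgen <- NA_real_
  pg <- x$pgen[!is.na(x$pgen)]
  if (any(pg < 0 | pg > 1)) {
    abort("pgen values must lie in [0, 1]", class = "pubsim_validation_error")
  }
  x
}

# canonical single-string identity used for set operations on receptors
receptor_key <- function(x) {
  paste(x$junction_aa, x$v_call, x$j_call, sep = "\r")
}
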