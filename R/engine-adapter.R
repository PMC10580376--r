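#' Adapter for an external V(D)J recombination engine
#'
#' Wraps the OLGA command-line tools (`olga-generate_sequences`,
#' `olga-compute_pgen`) behind the same `engine_sample()` / `engine_pgen()`
#' contract as the built-in toy model, so downstream code is agnostic to the
#' provider. OLGA supplies four default generative models; only those are
#' accepted. The external engine is an optional dependency: constructing the
#' adapter when it is not installed raises a dependency error naming it,
#' rather than failing later mid-simulation.
#'
#' @param model_name One of `"humanTRB"`, `"humanTRA"`, `"humanIGH"`,
#'   `"mouseIGH"` (the engine's default models).
#' @return An object of class `olga_engine` implementing the engine contract.
#' @export
olga_engine <- function(model_name = "humanTRB") {
  supported <- c("humanTRB", "humanTRA", "humanIGH", "mouseIGH")
  if (!model_name %in% supported) {
    abort(paste0("unsupported V(D)J model '", model_name,
                 "'; the external engine ships: ",
                 paste(supported, collapse = ", ")),
          class = "pubsim_config_error")
  }
  gen <- Sys.which("olga-generate_sequences")
  pg <- Sys.which("olga-compute_pgen")
  if (!nzchar(gen) || !nzchar(pg)) {
    abort(paste0(
      "the external V(D)J engine OLGA is not installed ",
      "(olga-generate_sequences / olga-compute_pgen not found on PATH); ",
      "install the 'olga' Python package or use the built-in toy engine"
    ), class = "pubsim_dependency_error")
  }
  structure(list(model_name = model_name, generate_bin = gen, pgen_bin = pg),
            class = c("olga_engine", "pubsim_engine"))
}

#' @rdname olga_engine
#' @inheritParams engine_sample
#' @export
engine_sample.olga_engine <- function(engine, n, seed) {
  out <- withr::local_tempfile(fileext = ".tsv")
  status <- system2(engine$generate_bin,
                    c("--" , engine$model_name, "-o", out, "-n", format(n),
                      "--seed", format(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    abort("external engine failed while generating sequences",
          class = "pubsim_dependency_error")
  }
  raw <- readr::read_tsv(out, col_names = c("nt", "junction_aa", "v_call",
                                            "j_call"),
                         show_col_types = FALSE)
  rec <- tibble(junction_aa = raw$junction_aa, v_call = raw$v_call,
                j_call = raw$j_call, pgen = NA_real_)
  rec$pgen <- engine_pgen(engine, rec)
  validate_receptors(rec)
}

#' @rdname olga_engine
#' @inheritParams engine_pgen
#' @export
engine_pgen.olga_engine <- function(engine, receptors) {
  receptors <- validate_receptors(receptors)
  infile <- withr::local_tempfile(fileext = ".tsv")
  outfile <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(receptors[, c("junction_aa", "v_call", "j_call")], infile,
                   col_names = FALSE)
  status <- system2(engine$pgen_bin,
                    c("--", engine$model_name, "-i", infile, "-o", outfile,
                      "--v_mask_index", "1", "--j_mask_index", "2",
                      "--seq_in", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    abort("external engine failed while computing generation probabilities",
          class = "pubsim_dependency_error")
  }
  res <- readr::read_tsv(outfile, col_names = FALSE, show_col_types = FALSE)
  p <- as.double(res[[2]])
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("external engine returned probabilities outside [0, 1]",
          class = "pubsim_validation_error")
  }
  p
}
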