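#' Read and write repertoire files (AIRR Rearrangement TSV)
#'
#' A repertoire file is a TSV with at least the columns `junction_aa`,
#' `v_call`, `j_call` (extra columns are preserved on round trip where
#' possible). A repertoire is a set of receptors: duplicated rows are
#' collapsed on read with a logged count. Written files carry a
#' `duplicate_count` column fixed at 1 (clonal frequencies are not
#' simulated).
#'
#' @param path Path to the TSV file.
#' @return `read_repertoire_tsv()` returns a receptor tibble;
#'   `write_repertoire_tsv()` returns `path` invisibly.
#' @export
read_repertoire_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("junction_aa", "v_call", "j_call")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("repertoire file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pubsim_schema_error")
  }
  bad <- which(!is_valid_aa(df$junction_aa))
  if (length(bad) > 0) {
    abort(paste0("malformed junction_aa in ", path, " at line(s): ",
                 paste(head(bad + 1, 10), collapse = ", ")),
          class = "pubsim_schema_error")
  }
  keys <- receptor_key(df)
  ndup <- sum(duplicated(keys))
  if (ndup > 0) {
    inform(paste0(path, ": collapsed ", ndup, " duplicated receptor row(s)"))
    df <- df[!duplicated(keys), ]
  }
  validate_receptors(df)
}

#' @rdname read_repertoire_tsv
#' @param receptors A receptor tibble.
#' @export
write_repertoire_tsv <- function(receptors, path) {
  receptors <- validate_receptors(receptors)
  out <- receptors
  if (!"duplicate_count" %in% names(out)) out$duplicate_count <- 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write cohort metadata
#'
#' Metadata is a TSV with columns `repertoire_id`, `filename`, `label`.
#' Labels are the strings `"positive"`/`"negative"` (numeric 1/0 accepted on
#' read); unlabeled baseline datasets use `NA`.
#'
#' @param path TSV path.
#' @param check_files When `TRUE`, fail fast if a referenced repertoire file
#'   does not exist next to the metadata file.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path, check_files = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          repertoire_id = readr::col_character(),
                          filename = readr::col_character(),
                          label = readr::col_character()
                        ))
  required <- c("repertoire_id", "filename", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pubsim_schema_error")
  }
  df$label[df$label %in% "1"] <- "positive"
  df$label[df$label %in% "0"] <- "negative"
  bad <- !(df$label %in% c("positive", "negative") | is.na(df$label))
  if (any(bad)) {
    abort(paste0("labels outside {positive, negative, 1, 0, NA}: ",
                 paste(unique(df$label[bad]), collapse = ", ")),
          class = "pubsim_validation_error")
  }
  if (check_files) {
    paths <- file.path(dirname(path), df$filename)
    absent <- df$filename[!file.exists(paths)]
    if (length(absent) > 0) {
      abort(paste0("metadata references missing repertoire file(s): ",
                   paste(head(absent, 5), collapse = ", ")),
            class = "pubsim_validation_error")
    }
  }
  df
}

#' @rdname read_metadata
#' @param metadata A metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read and write a ground-truth signal manifest
#'
#' The manifest records every (signal sequence, repertoire) placement as a
#' TSV with columns `junction_aa`, `v_call`, `j_call`, `repertoire_id`; it
#' round-trips exactly.
#'
#' @param manifest A manifest tibble.
#' @param path TSV path.
#' @return The manifest tibble (read) or `path` invisibly (write).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write and read a full repertoire dataset directory
#'
#' Lays a `repertoire_dataset` out on disk as one AIRR Rearrangement TSV per
#' repertoire plus `metadata.tsv`, `manifest.tsv` and a provenance log
#' `provenance.json` (config hash, seed, stage list, timings).
#'
#' @param dataset A `repertoire_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `repertoire_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "repertoire_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_rep <- split(dataset$receptors, dataset$receptors$repertoire_id)
  for (i in seq_len(nrow(dataset$metadata))) {
    rid <- dataset$metadata$repertoire_id[i]
    rec <- by_rep[[rid]]
    if (is.null(rec)) rec <- dataset$receptors[0, ]
    write_repertoire_tsv(
      rec[, setdiff(names(rec), "repertoire_id")],
      file.path(dir, dataset$metadata$filename[i])
    )
  }
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  write_provenance(dataset$provenance, file.path(dir, "provenance.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  metadata <- read_metadata(file.path(dir, "metadata.tsv"), check_files = TRUE)
  recs <- purrr::map2(metadata$repertoire_id, metadata$filename,
                      function(rid, fn) {
                        r <- read_repertoire_tsv(file.path(dir, fn))
                        r$repertoire_id <- rid
                        r[, c("repertoire_id", "junction_aa", "v_call",
                              "j_call", "pgen")]
                      })
  manifest_path <- file.path(dir, "manifest.tsv")
  manifest <- if (file.exists(manifest_path)) read_manifest(manifest_path)
  prov_path <- file.path(dir, "provenance.json")
  provenance <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_repertoire_dataset(bind_rows(recs), metadata, manifest, provenance)
}

# small stable hash (FNV-1a over the deparsed semantic config) so the
# provenance log records which configuration produced an output tree
config_hash <- function(config) {
  x <- config
  x$seed <- NULL  # the seed is logged separately
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 4294967296
  sprintf("%010.0f", h)
}

write_provenance <- function(provenance, path) {
  pr <- provenance
  pr$public_keys <- NULL  # internal bookkeeping, too bulky for the log
  if (!is.null(pr$config)) pr$config_hash <- config_hash(pr$config)
  jsonlite::write_json(pr, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write signal pools
#'
#' A pool file is a TSV with columns `junction_aa`, `v_call`, `j_call`,
#' `pgen`.
#'
#' @param path TSV path.
#' @return A receptor tibble.
#' @export
read_pool_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_receptors(df)
}

#' Read a simulation run configuration from YAML
#'
#' The YAML file carries the [sim_config()] fields plus the file paths the
#' workflow needs (`signal_pool`, `signal_model`, `public_model`,
#' `toy_model`) and optional `audit_thresholds`. Unknown keys are rejected
#' so typos fail fast.
#'
#' @param path YAML path.
#' @return A list with elements `config` (a [sim_config()]) and `paths`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  config_keys <- c("n_repertoires", "positive_fraction", "depth",
                   "depth_spread", "public_fraction", "witness_rate",
                   "n_signal_pool_used", "signal_denominator", "seed")
  path_keys <- c("signal_pool", "signal_model", "public_model", "toy_model",
                 "engine", "audit_thresholds")
  unknown <- setdiff(names(y), c(config_keys, path_keys))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "pubsim_config_error")
  }
  cfg <- do.call(sim_config, y[intersect(names(y), config_keys)])
  pths <- y[intersect(names(y), path_keys)]
  for (k in c("signal_pool", "signal_model", "public_model", "toy_model")) {
    if (!is.null(pths[[k]]) && !file.exists(pths[[k]])) {
      abort(paste0("config path '", k, "' does not exist: ", pths[[k]]),
            class = "pubsim_config_error")
    }
  }
  list(config = cfg, paths = pths)
}
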