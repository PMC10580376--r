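#' Run the simulation workflow end-to-end or stage-by-stage
#'
#' The four stages are (i) feasibility assessment, (ii) baseline repertoire
#' generation, (iii) public-component correction and (iv) signal
#' implantation. `mode = "full"` chains i -> ii -> iii -> iv; the partial
#' modes emit their stage's artifact only. Every run writes its artifacts
#' under `out_dir` together with a provenance log; nothing outside `out_dir`
#' is touched.
#'
#' @param config A [sim_config()].
#' @param mode One of `"feasibility"`, `"baseline"`, `"public_correction"`,
#'   `"full"`.
#' @param out_dir Output directory.
#' @param engine A generative engine (required for all modes but
#'   `"feasibility"`).
#' @param signal_model,public_model [incidence_model()] components (defaults:
#'   the synthetic fixtures from [synthetic_incidence_models()]).
#' @param signal_pool Receptor tibble with pgen (required for
#'   `"feasibility"` and `"full"` with a positive witness rate).
#' @param override_feasibility Passed to [implant_signals()].
#' @return The final stage's object (a `feasibility_report` or a
#'   `repertoire_dataset`), invisibly; artifacts are on disk.
#' @export
run_workflow <- function(config,
                         mode = c("full", "feasibility", "baseline",
                                  "public_correction"),
                         out_dir, engine = NULL,
                         signal_model = NULL, public_model = NULL,
                         signal_pool = NULL,
                         override_feasibility = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  models <- NULL
  if (is.null(signal_model) || is.null(public_model)) {
    models <- synthetic_incidence_models()
  }
  signal_model <- signal_model %||% models$signal
  public_model <- public_model %||% models$public
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(label, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[label]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    out
  }
  needs_pool <- mode == "feasibility" ||
    (mode == "full" && config$witness_rate > 0)
  if (needs_pool && is.null(signal_pool)) {
    abort("this mode needs a signal pool but none was supplied",
          class = "pubsim_config_error")
  }
  if (mode != "feasibility" && is.null(engine)) {
    abort("this mode needs a generative engine but none was supplied",
          class = "pubsim_config_error")
  }

  report <- NULL
  if (mode %in% c("feasibility", "full") && !is.null(signal_pool)) {
    report <- clock("feasibility",
                    assess_feasibility(signal_pool, config, signal_model))
    jsonlite::write_json(
      c(glance(report), list(guidance = report$guidance)),
      file.path(out_dir, "feasibility.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    readr::write_tsv(tidy(report),
                     file.path(out_dir, "feasibility_caps.tsv"),
                     progress = FALSE)
  }
  if (mode == "feasibility") {
    write_provenance(list(config = unclass(config), seed = config$seed,
                          stages = "feasibility", timings = timings),
                     file.path(out_dir, "provenance.json"))
    return(invisible(report))
  }

  dataset <- clock("baseline", generate_baseline(config, engine))
  if (mode %in% c("public_correction", "full")) {
    dataset <- clock("public_correction",
                     correct_public_component(config, engine, public_model,
                                              baseline = dataset))
  }
  if (mode == "full") {
    dataset <- if (config$witness_rate > 0) {
      clock("implant",
            implant_signals(dataset, signal_pool, config, signal_model,
                            override_feasibility = override_feasibility))
    } else {
      # degenerate full run: labels only, empty manifest
      clock("implant",
            with_stage_seed(config$seed, "implant", {
              pos <- sample(dataset$metadata$repertoire_id, config$n_positive)
              md <- mutate(dataset$metadata,
                           label = ifelse(.data$repertoire_id %in% pos,
                                          "positive", "negative"))
              pr <- dataset$provenance
              pr$stages <- c(pr$stages, "implant")
              new_repertoire_dataset(dataset$receptors, md, NULL, pr)
            }))
    }
  }
  dataset$provenance$timings <- timings
  write_dataset(dataset, out_dir)
  invisible(dataset)
}
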