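#' Binnings for generation probability and population incidence
#'
#' Both binnings use half-open intervals `[left, right)` that include the
#' left endpoint and exclude the right one. Values below the first edge are
#' clamped into the first bin and values at or above the last edge into the
#' last bin, so every finite value maps to exactly one bin.
#'
#' The default generation-probability binning groups log10(pgen) into four
#' ranges — below -12, `[-12, -9)`, `[-9, -6)` and `[-6, 0]` — covering the dynamic
#' range of receptor generation probabilities; the default incidence binning
#' uses edges 0, 0.02, 0.05, 0.1, 0.2, 0.3, 1 (sharing below 2% of the cohort
#' is by far the most common regime for public sequences).
#'
#' @param log10_edges Ascending numeric vector of log10-pgen breakpoints
#'   (length >= 2; may start at `-Inf`).
#' @return An object of class `pgen_binning` / `incidence_binning`.
#' @export
pgen_binning <- function(log10_edges = c(-Inf, -12, -9, -6, 0)) {
  if (length(log10_edges) < 2 || is.unsorted(log10_edges, strictly = TRUE)) {
    abort("log10_edges must be strictly increasing with length >= 2",
          class = "pubsim_config_error")
  }
  structure(list(edges = as.double(log10_edges)), class = "pgen_binning")
}

#' @rdname pgen_binning
#' @param edges Ascending numeric vector of incidence-fraction breakpoints
#'   in `[0, 1]`.
#' @export
incidence_binning <- function(edges = c(0, 0.02, 0.05, 0.1, 0.2, 0.3, 1)) {
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE) ||
      any(edges < 0) || any(edges > 1)) {
    abort("incidence edges must be strictly increasing fractions in [0, 1]",
          class = "pubsim_config_error")
  }
  structure(list(edges = as.double(edges)), class = "incidence_binning")
}

# map values to bin index with clamping into [1, n_bins]
bin_index <- function(x, edges) {
  findInterval(x, edges, all.inside = TRUE)
}

pgen_bin_of <- function(binning, pgen) {
  bin_index(log10(pmax(pgen, .Machine$double.xmin)), binning$edges)
}

bin_label <- function(edges) {
  n <- length(edges) - 1
  sprintf("[%s, %s)", format(edges[-(n + 1)], trim = TRUE),
          format(edges[-1], trim = TRUE))
}

#' Construct an incidence model
#'
#' An incidence model is a binned empirical distribution of the population
#' incidence fraction of public sequences, conditional on their generation
#' probability bin: `table[i, j]` is the probability that a public sequence
#' whose pgen falls in bin `i` is carried by a fraction of repertoires
#' falling in incidence bin `j`. Rows with no training data are marked empty
#' via `row_counts` and fall back to the nearest trained row when sampled.
#'
#' @param pgen_binning A [pgen_binning()].
#' @param incidence_binning An [incidence_binning()].
#' @param table Numeric matrix, rows = pgen bins, columns = incidence bins;
#'   every row with training data must sum to 1 within 1e-9.
#' @param row_counts Integer vector of training sequences per pgen bin
#'   (0 marks an empty row).
#' @param component_label `"signal"` or `"public"`.
#' @return An object of class `incidence_model`.
#' @export
incidence_model <- function(pgen_binning, incidence_binning, table,
                            row_counts, component_label) {
  stopifnot(inherits(pgen_binning, "pgen_binning"),
            inherits(incidence_binning, "incidence_binning"))
  table <- as.matrix(table)
  n_p <- length(pgen_binning$edges) - 1
  n_i <- length(incidence_binning$edges) - 1
  if (!all(dim(table) == c(n_p, n_i))) {
    abort(paste0("table must be ", n_p, " x ", n_i, " for these binnings"),
          class = "pubsim_validation_error")
  }
  if (any(table < 0 | table > 1)) {
    abort("table entries must lie in [0, 1]", class = "pubsim_validation_error")
  }
  row_counts <- as.integer(row_counts)
  stopifnot(length(row_counts) == n_p)
  for (i in which(row_counts > 0)) {
    if (abs(sum(table[i, ]) - 1) > 1e-9) {
      abort(paste0("row ", i, " of the incidence table sums to ",
                   format(sum(table[i, ]), digits = 15), ", not 1"),
            class = "pubsim_validation_error")
    }
  }
  if (!component_label %in% c("signal", "public")) {
    abort("component_label must be 'signal' or 'public'",
          class = "pubsim_validation_error")
  }
  structure(
    list(pgen_binning = pgen_binning, incidence_binning = incidence_binning,
         table = table, row_counts = row_counts,
         component_label = component_label),
    class = "incidence_model"
  )
}

#' @export
print.incidence_model <- function(x, ...) {
  cat("<incidence_model> component:", x$component_label, "\n")
  cat("  pgen bins (log10):", paste(x$pgen_binning$edges, collapse = ", "), "\n")
  cat("  incidence bins:", paste(x$incidence_binning$edges, collapse = ", "), "\n")
  cat("  training sequences per row:", paste(x$row_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate incidence models from observed sharing counts
#'
#' Learns the empirical relation between generation probability and
#' population incidence from a labeled cohort, separately for designated
#' signal sequences and for all remaining public sequences. Each unique
#' public sequence (observed in at least two repertoires) contributes once to
#' exactly one (pgen bin, incidence bin) cell of exactly one component. The
#' signal component's incidence fractions are computed against the
#' positive-class repertoire count; the public component's against the total
#' repertoire count.
#'
#' @param occurrences Receptor tibble with columns `junction_aa`, `v_call`,
#'   `j_call`, `pgen` and `count` (number of repertoires carrying the
#'   sequence; all counts must be >= 2).
#' @param total_repertoires Total number of repertoires in the cohort.
#' @param positive_repertoires Number of positive-class repertoires (the
#'   signal component's denominator). Defaults to `total_repertoires`.
#' @param pgen_binning,incidence_binning Binnings (defaults as documented).
#' @param signal_keys Character vector of receptor keys (see details) or a
#'   receptor tibble of the sequences to treat as signal; everything else is
#'   calibrated into the public component.
#' @return A list with elements `signal` and `public`, each an
#'   [incidence_model()].
#' @export
calibrate_incidence <- function(occurrences, total_repertoires,
                                positive_repertoires = total_repertoires,
                                pgen_binning = pubsim::pgen_binning(),
                                incidence_binning = pubsim::incidence_binning(),
                                signal_keys = character()) {
  occurrences <- as_tibble(occurrences)
  stopifnot("count" %in% names(occurrences))
  occurrences <- validate_receptors(occurrences)
  miss <- which(is.na(occurrences$pgen))
  if (length(miss) > 0) {
    abort(paste0("sequences missing a pgen (rows): ",
                 paste(head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) " ..." else ""),
          class = "pubsim_validation_error")
  }
  if (any(occurrences$count < 2)) {
    abort("public sequences must have count >= 2 (shared by definition)",
          class = "pubsim_validation_error")
  }
  if (is.data.frame(signal_keys)) signal_keys <- receptor_key(signal_keys)
  keys <- receptor_key(occurrences)
  if (anyDuplicated(keys)) {
    abort("occurrences must contain one row per unique receptor",
          class = "pubsim_validation_error")
  }
  is_signal <- keys %in% signal_keys
  build <- function(df, denominator, label) {
    n_p <- length(pgen_binning$edges) - 1
    n_i <- length(incidence_binning$edges) - 1
    tab <- matrix(0, n_p, n_i)
    counts <- integer(n_p)
    if (nrow(df) > 0) {
      if (any(df$count > denominator)) {
        abort(paste0(label, " component: some counts exceed the denominator ",
                     denominator),
              class = "pubsim_validation_error")
      }
      pb <- pgen_bin_of(pgen_binning, df$pgen)
      ib <- bin_index(df$count / denominator, incidence_binning$edges)
      for (r in seq_len(nrow(df))) tab[pb[r], ib[r]] <- tab[pb[r], ib[r]] + 1
      counts <- as.integer(tabulate(pb, n_p))
      nz <- counts > 0
      tab[nz, ] <- tab[nz, , drop = FALSE] / counts[nz]
    }
    incidence_model(pgen_binning, incidence_binning, tab, counts, label)
  }
  list(
    signal = build(occurrences[is_signal, ], positive_repertoires, "signal"),
    public = build(occurrences[!is_signal, ], total_repertoires, "public")
  )
}

# resolve the table row used for a pgen bin: empty rows borrow the nearest
# trained row, preferring lower pgen (conservative: lower sharing)
resolve_row <- function(model, bins) {
  trained <- which(model$row_counts > 0)
  if (length(trained) == 0) {
    abort(paste0("incidence model (", model$component_label,
                 ") has no trained rows and cannot be used"),
          class = "pubsim_model_error")
  }
  vapply(bins, function(b) {
    if (model$row_counts[b] > 0) return(b)
    lower <- trained[trained < b]
    pick <- if (length(lower) > 0) max(lower) else min(trained[trained > b])
    pick
  }, integer(1))
}

#' Draw population-incidence counts for public sequences
#'
#' For each generation probability, picks the pgen bin's row of the model,
#' draws an incidence bin from the row's categorical distribution, draws an
#' incidence fraction uniformly within the bin, converts to a repertoire
#' count as `floor(fraction * denominator)`, and clamps the count into
#' `[2, denominator_repertoires]`. The floor keeps a drawn count's implied
#' fraction inside its bin (rounding upward would systematically push
#' fractions just under a bin edge across it, so recalibration of simulated
#' counts would not recover the generating model); the >= 2 floor reflects
#' that a public sequence is by definition shared.
#'
#' @param model An [incidence_model()].
#' @param pgen Numeric vector of generation probabilities.
#' @param denominator_repertoires The repertoire count the fractions refer to.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (callers inside the workflow seed per stage).
#' @return Integer vector of counts, all in `[2, denominator_repertoires]`.
#' @export
sample_incidence_count <- function(model, pgen, denominator_repertoires,
                                   seed = NULL) {
  stopifnot(inherits(model, "incidence_model"), denominator_repertoires >= 2)
  draw <- function() {
    bins <- pgen_bin_of(model$pgen_binning, pgen)
    rows <- resolve_row(model, bins)
    if (any(rows != bins)) {
      warn(paste0("empty incidence row(s) for ", sum(rows != bins),
                  " sequence(s); borrowing nearest trained row"))
    }
    edges <- model$incidence_binning$edges
    n_i <- length(edges) - 1
    ib <- vapply(rows, function(r) {
      sample.int(n_i, 1, prob = model$table[r, ])
    }, integer(1))
    frac <- runif(length(ib), edges[ib], edges[ib + 1])
    cnt <- floor(frac * denominator_repertoires)
    cap <- floor(max_incidence_fraction(model, pgen) * denominator_repertoires)
    # the cap guard is belt-and-braces (floor already stays below it); the
    # >= 2 publicness floor takes precedence when a cap falls below 2
    pmin(pmax(pmin(cnt, cap), 2), denominator_repertoires)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Maximum achievable incidence fraction under a model
#'
#' Returns, for each generation probability, the right edge of the highest
#' incidence bin with nonzero probability in the pgen bin's row — the
#' fraction of the cohort a sequence with that pgen can at most be seen in.
#'
#' @inheritParams sample_incidence_count
#' @return Numeric vector of fractions in `(0, 1]`.
#' @export
max_incidence_fraction <- function(model, pgen) {
  stopifnot(inherits(model, "incidence_model"))
  bins <- pgen_bin_of(model$pgen_binning, pgen)
  rows <- resolve_row(model, bins)
  edges <- model$incidence_binning$edges
  vapply(rows, function(r) {
    nz <- which(model$table[r, ] > 0)
    edges[max(nz) + 1]
  }, numeric(1))
}

#' Save and load incidence models
#'
#' Models round-trip exactly through a versioned, human-readable JSON file
#' (fields: `version`, `component_label`, `pgen_log10_edges`,
#' `incidence_edges`, `rows`, `row_counts`). A TSV layout (one line per pgen
#' bin: `pgen_left  pgen_right  n_train  <one column per incidence bin>`,
#' with `component_label` and incidence edges carried in `#`-comment header
#' lines) is also accepted for hand editing.
#'
#' @param model An [incidence_model()].
#' @param path Output file; extension `.json` or `.tsv` selects the format.
#' @return `write_incidence_model()` returns `path` invisibly;
#'   `read_incidence_model()` returns an [incidence_model()].
#' @export
write_incidence_model <- function(model, path) {
  stopifnot(inherits(model, "incidence_model"))
  if (grepl("\\.tsv$", path)) {
    edges <- model$incidence_binning$edges
    hdr <- c(paste0("# pubsim incidence model v1"),
             paste0("# component_label\t", model$component_label),
             paste0("# incidence_edges\t", paste(edges, collapse = "\t")))
    pe <- model$pgen_binning$edges
    body <- vapply(seq_len(nrow(model$table)), function(i) {
      paste(c(pe[i], pe[i + 1], model$row_counts[i],
              format(model$table[i, ], digits = 17)), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    jsonlite::write_json(
      list(version = 1L, component_label = model$component_label,
           pgen_log10_edges = model$pgen_binning$edges,
           incidence_edges = model$incidence_binning$edges,
           row_counts = model$row_counts,
           rows = apply(model$table, 1, identity, simplify = FALSE)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_incidence_model
#' @export
read_incidence_model <- function(path) {
  if (grepl("\\.tsv$", path)) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    get_field <- function(key) {
      ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
      if (length(ln) != 1) {
        abort(paste0("model TSV missing '# ", key, "' header"),
              class = "pubsim_validation_error")
      }
      strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t")[[1]]
    }
    label <- get_field("component_label")
    iedges <- as.double(get_field("incidence_edges"))
    rows <- do.call(rbind, lapply(strsplit(body, "\t"), as.double))
    pedges <- c(rows[, 1], rows[nrow(rows), 2])
    incidence_model(pgen_binning(pedges), incidence_binning(iedges),
                    rows[, -(1:3), drop = FALSE], as.integer(rows[, 3]), label)
  } else {
    y <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(y$version) || y$version != 1) {
      abort(paste0("unknown incidence-model file version: ",
                   y$version %||% "<missing>"),
            class = "pubsim_validation_error")
    }
    tab <- if (is.list(y$rows)) do.call(rbind, y$rows) else y$rows
    # JSON has no -Inf literal; accept the string form
    pe <- suppressWarnings(as.double(y$pgen_log10_edges))
    incidence_model(pgen_binning(pe), incidence_binning(y$incidence_edges),
                    tab, y$row_counts, y$component_label)
  }
}

#' @export
tidy.incidence_model <- function(x, ...) {
  pe <- x$pgen_binning$edges
  ie <- x$incidence_binning$edges
  n_p <- length(pe) - 1
  n_i <- length(ie) - 1
  tibble(
    component = x$component_label,
    pgen_bin = rep(bin_label(pe), each = n_i),
    pgen_log10_left = rep(pe[-(n_p + 1)], each = n_i),
    pgen_log10_right = rep(pe[-1], each = n_i),
    incidence_bin = rep(bin_label(ie), times = n_p),
    incidence_left = rep(ie[-(n_i + 1)], times = n_p),
    incidence_right = rep(ie[-1], times = n_p),
    prob = as.vector(t(x$table)),
    n_train = rep(x$row_counts, each = n_i)
  )
}

#' @export
glance.incidence_model <- function(x, ...) {
  tibble(
    component = x$component_label,
    n_pgen_bins = length(x$pgen_binning$edges) - 1,
    n_incidence_bins = length(x$incidence_binning$edges) - 1,
    n_train = sum(x$row_counts),
    n_empty_rows = sum(x$row_counts == 0)
  )
}

#' @export
autoplot.incidence_model <- function(object, ...) {
  d <- tidy(object)
  d$incidence_bin <- factor(d$incidence_bin, levels = unique(d$incidence_bin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pgen_bin, y = .data$prob,
                                  fill = .data$incidence_bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = "generation probability bin (log10)",
      y = "fraction of sequences",
      fill = "population incidence",
      title = paste0("Incidence distribution by pgen bin (",
                     object$component_label, " component)")
    ) +
    ggplot2::theme_minimal()
}

#' Synthetic default incidence models
#'
#' A pair of invented signal/public incidence models for examples and tests.
#' Their shape imitates what calibration on a large antigen-experienced
#' cohort produces — the bulk of non-signal public sequences shared by fewer
#' than 2% of repertoires with sharing increasing with generation
#' probability, signal sequences shifted toward higher incidence, and no
#' sequence seen in more than 30% of the cohort — but the numbers are
#' synthetic, not calibrated on any real dataset. Users simulating from real
#' cohorts should calibrate with [calibrate_incidence()].
#'
#' @return A list with elements `signal` and `public`.
#' @export
synthetic_incidence_models <- function() {
  pb <- pgen_binning()
  ib <- incidence_binning()
  public <- rbind(
    c(0.980, 0.015, 0.005, 0.000, 0.000, 0),
    c(0.960, 0.025, 0.010, 0.005, 0.000, 0),
    c(0.900, 0.060, 0.025, 0.010, 0.005, 0),
    c(0.800, 0.100, 0.060, 0.030, 0.010, 0)
  )
  signal <- rbind(
    c(0.35, 0.25, 0.20, 0.12, 0.08, 0),
    c(0.30, 0.25, 0.20, 0.15, 0.10, 0),
    c(0.25, 0.25, 0.20, 0.18, 0.12, 0),
    c(0.20, 0.20, 0.25, 0.20, 0.15, 0)
  )
  list(
    signal = incidence_model(pb, ib, signal, rep(1000L, 4), "signal"),
    public = incidence_model(pb, ib, public, rep(1000L, 4), "public")
  )
}
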