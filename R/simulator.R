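#' Simulation configuration
#'
#' Bundles the user-facing knobs of a cohort simulation. The witness rate is
#' specified as the mean number of signal sequences per positive repertoire;
#' its per-10^5-receptors normalization (`witness_rate / depth * 1e5`) is
#' derived and reported alongside.
#'
#' @param n_repertoires Number of repertoires in the cohort.
#' @param positive_fraction Fraction of repertoires labeled positive
#'   (in (0, 1)).
#' @param depth Target unique receptors per repertoire (the mean).
#' @param depth_spread Allowed half-width around `depth`; per-repertoire
#'   targets are drawn uniformly in `depth +/- depth_spread` (default 0:
#'   exact depth).
#' @param public_fraction Fraction of the dataset's unique sequences made
#'   public (default 0.10, matching sharing levels in experimental cohorts).
#' @param witness_rate Mean signal sequences per positive repertoire (>= 0).
#' @param n_signal_pool_used Optional cap on how many pool sequences may be
#'   used as signal.
#' @param signal_denominator `"positive"` (default) or `"total"`: the
#'   repertoire count against which signal incidence fractions are drawn.
#' @param seed Integer top-level seed; every stage derives its own stream.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_repertoires = 200, positive_fraction = 0.5, depth = 1000,
#'            witness_rate = 5, seed = 1)
sim_config <- function(n_repertoires, positive_fraction = 0.5, depth,
                       depth_spread = 0, public_fraction = 0.10,
                       witness_rate = 0, n_signal_pool_used = NULL,
                       signal_denominator = c("positive", "total"),
                       seed = 1L) {
  signal_denominator <- match.arg(signal_denominator)
  stopifnot(n_repertoires >= 1, depth >= 1, depth_spread >= 0,
            witness_rate >= 0)
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    abort("positive_fraction must lie strictly between 0 and 1",
          class = "pubsim_config_error")
  }
  if (public_fraction < 0 || public_fraction > 1) {
    abort("public_fraction must lie in [0, 1]", class = "pubsim_config_error")
  }
  n_positive <- as.integer(round_half_up(positive_fraction * n_repertoires))
  structure(list(
    n_repertoires = as.integer(n_repertoires),
    positive_fraction = positive_fraction,
    n_positive = n_positive,
    depth = depth,
    depth_spread = depth_spread,
    public_fraction = public_fraction,
    witness_rate = witness_rate,
    witness_rate_per_1e5 = witness_rate / depth * 1e5,
    n_signal_pool_used = n_signal_pool_used,
    signal_denominator = signal_denominator,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  repertoires:", x$n_repertoires, "(", x$n_positive, "positive )\n")
  cat("  depth:", x$depth, "+/-", x$depth_spread, "\n")
  cat("  public fraction:", x$public_fraction, "\n")
  cat(sprintf("  witness rate: %g per positive repertoire (%.3g per 1e5 receptors)\n",
              x$witness_rate, x$witness_rate_per_1e5))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

new_repertoire_dataset <- function(receptors, metadata, manifest = NULL,
                                   provenance = list()) {
  if (is.null(manifest)) {
    manifest <- tibble(junction_aa = character(), v_call = character(),
                       j_call = character(), repertoire_id = character())
  }
  stopifnot(!anyDuplicated(metadata$repertoire_id),
            all(manifest$repertoire_id %in% metadata$repertoire_id))
  structure(list(receptors = as_tibble(receptors),
                 metadata = as_tibble(metadata),
                 manifest = as_tibble(manifest),
                 provenance = provenance),
            class = "repertoire_dataset")
}

#' @export
print.repertoire_dataset <- function(x, ...) {
  cat("<repertoire_dataset>", nrow(x$metadata), "repertoires,",
      nrow(x$receptors), "receptor rows\n")
  lab <- table(x$metadata$label, useNA = "ifany")
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  cat("  manifest placements:", nrow(x$manifest), "\n")
  invisible(x)
}

#' @export
glance.repertoire_dataset <- function(x, ...) {
  depths <- dplyr::count(x$receptors, .data$repertoire_id)$n
  tibble(
    n_repertoires = nrow(x$metadata),
    n_positive = sum(x$metadata$label == "positive", na.rm = TRUE),
    mean_depth = mean(depths),
    n_unique_sequences = dplyr::n_distinct(receptor_key(x$receptors)),
    n_manifest = nrow(x$manifest)
  )
}

#' Assess the feasibility of a desired witness rate
#'
#' The required signal total is `round(n_positive * witness_rate)`. Each pool
#' sequence can be carried by at most
#' `floor(max_incidence_fraction(signal_model, pgen) * n_repertoires)`
#' repertoires (and never more than the positive repertoire count, since
#' implanted carriers are distinct positive repertoires). If the summed caps
#' fall short of the required total, the desired witness rate is infeasible
#' with this pool, and the report's guidance quantifies the shortfall.
#'
#' @param signal_pool Receptor tibble with `pgen` set on every row.
#' @param config A [sim_config()].
#' @param signal_model The signal-component [incidence_model()].
#' @return An object of class `feasibility_report`.
#' @export
assess_feasibility <- function(signal_pool, config, signal_model) {
  stopifnot(inherits(config, "sim_config"))
  signal_pool <- validate_receptors(signal_pool)
  if (nrow(signal_pool) == 0) {
    abort("signal pool is empty", class = "pubsim_validation_error")
  }
  if (anyNA(signal_pool$pgen)) {
    abort("every signal-pool receptor needs a pgen",
          class = "pubsim_validation_error")
  }
  if (!is.null(config$n_signal_pool_used)) {
    signal_pool <- head(signal_pool, config$n_signal_pool_used)
  }
  if (any(signal_pool$pgen == 0)) {
    warn(paste0(sum(signal_pool$pgen == 0), " pool sequence(s) have pgen 0 ",
                "and can never be made public under the incidence model"))
  }
  required_total <- as.integer(round_half_up(config$n_positive *
                                               config$witness_rate))
  caps <- integer(nrow(signal_pool))
  nonzero <- signal_pool$pgen > 0
  if (any(nonzero)) {
    caps[nonzero] <- pmin(
      floor(max_incidence_fraction(signal_model, signal_pool$pgen[nonzero]) *
              config$n_repertoires),
      config$n_positive
    )
  }
  achievable_total <- as.integer(sum(caps))
  feasible <- achievable_total >= required_total
  guidance <- if (feasible) {
    sprintf("feasible: achievable total %d >= required total %d",
            achievable_total, required_total)
  } else {
    sprintf(paste0(
      "infeasible: the pool of %d sequence(s) can contribute at most %d ",
      "signal instances but %d are required (%d positive repertoires x ",
      "witness rate %g); supply a larger pool or lower the witness rate ",
      "(shortfall: %d instances)"),
      nrow(signal_pool), achievable_total, required_total, config$n_positive,
      config$witness_rate, required_total - achievable_total)
  }
  structure(list(
    required_total = required_total,
    achievable_total = achievable_total,
    per_sequence_caps = mutate(
      signal_pool[, c("junction_aa", "v_call", "j_call", "pgen")],
      cap = as.integer(caps)),
    feasible = feasible,
    guidance = guidance
  ), class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("<feasibility_report>\n ", x$guidance, "\n")
  invisible(x)
}

#' @export
tidy.feasibility_report <- function(x, ...) x$per_sequence_caps

#' @export
glance.feasibility_report <- function(x, ...) {
  tibble(required_total = x$required_total,
         achievable_total = x$achievable_total,
         feasible = x$feasible,
         n_pool = nrow(x$per_sequence_caps))
}

# draw `target` unique receptors from an engine, topping up past duplicates
sample_unique <- function(engine, target, seed) {
  out <- engine_sample(engine, target, seed)
  out <- out[!duplicated(receptor_key(out)), ]
  tries <- 0
  while (nrow(out) < target) {
    tries <- tries + 1
    if (tries > 50) {
      abort(paste0("engine support too small to yield ", target,
                   " unique receptors"),
            class = "pubsim_resource_error")
    }
    extra <- engine_sample(engine, ceiling((target - nrow(out)) * 1.3) + 10,
                           seed + tries)
    out <- bind_rows(out, extra)
    out <- out[!duplicated(receptor_key(out)), ]
  }
  head(out, target)
}

#' Generate baseline (naive, fully private) repertoires
#'
#' Stage ii of the workflow: each repertoire is an independent i.i.d. sample
#' from the engine, deduplicated so that only unique sequences are retained,
#' with the unique count matching its per-repertoire depth target. The
#' result is unlabeled and carries no manifest; any sharing between
#' repertoires is the engine's own convergent recombination, nothing more.
#'
#' @param config A [sim_config()].
#' @param engine A generative engine.
#' @param seed Top-level seed (defaults to `config$seed`).
#' @return A `repertoire_dataset` with `label = NA` throughout.
#' @export
generate_baseline <- function(config, engine, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed <- derive_seed(seed, "baseline")
  n <- config$n_repertoires
  targets <- with_stage_seed(seed, "baseline-depths", {
    if (config$depth_spread > 0) {
      round_half_up(runif(n, config$depth - config$depth_spread,
                          config$depth + config$depth_spread))
    } else {
      rep(config$depth, n)
    }
  })
  ids <- sprintf("rep%04d", seq_len(n))
  reps <- purrr::map(seq_len(n), function(i) {
    recs <- sample_unique(engine, targets[i],
                          derive_seed(stage_seed, paste0("rep", i)))
    recs$repertoire_id <- ids[i]
    recs
  })
  new_repertoire_dataset(
    receptors = bind_rows(reps)[, c("repertoire_id", "junction_aa", "v_call",
                                    "j_call", "pgen")],
    metadata = tibble(repertoire_id = ids,
                      filename = paste0(ids, ".tsv"),
                      label = NA_character_),
    provenance = list(config = unclass(config), seed = seed,
                      stages = "baseline")
  )
}

# replace one private slot per addition: for every (key, repertoire)
# addition, remove one random resident sequence of that repertoire that is
# not protected (not itself public/signal), keeping depth constant
apply_replacements <- function(receptors, additions, protected_keys) {
  if (is.null(additions) || nrow(additions) == 0) return(receptors)
  keys <- receptor_key(receptors)
  removable_idx <- which(!(keys %in% protected_keys))
  idx_by_rep <- split(removable_idx, receptors$repertoire_id[removable_idx])
  add_per_rep <- table(additions$repertoire_id)
  drop_idx <- integer(0)
  overflow <- 0L
  for (rid in names(add_per_rep)) {
    cand <- idx_by_rep[[rid]]
    k <- add_per_rep[[rid]]
    avail <- length(cand)
    if (avail < k) {
      # degenerate configurations (e.g. public_fraction near 1) can exhaust
      # a repertoire's private slots; extend the repertoire instead
      overflow <- overflow + (k - avail)
      k <- avail
    }
    if (k > 0) drop_idx <- c(drop_idx, cand[sample.int(avail, k)])
  }
  if (overflow > 0) {
    inform(paste0(overflow, " placement(s) extended repertoires beyond ",
                  "their depth target: no private slots were left to replace"))
  }
  if (length(drop_idx) == 0) {
    return(bind_rows(receptors,
                     additions[, c("repertoire_id", "junction_aa", "v_call",
                                   "j_call", "pgen")]))
  }
  bind_rows(receptors[-drop_idx, ],
            additions[, c("repertoire_id", "junction_aa", "v_call",
                          "j_call", "pgen")])
}

# expand per-sequence carrier draws into one additions tibble
build_additions <- function(seqs, carrier_list) {
  times <- lengths(carrier_list)
  tibble(
    repertoire_id = unlist(carrier_list, use.names = FALSE) %||% character(),
    junction_aa = rep(seqs$junction_aa, times),
    v_call = rep(seqs$v_call, times),
    j_call = rep(seqs$j_call, times),
    pgen = rep(seqs$pgen, times)
  )
}

#' Correct the public component of a baseline dataset
#'
#' Stage iii: selects a `public_fraction` share of the dataset's unique
#' sequences as public and redraws each one's number of carrying repertoires
#' from the public incidence model given its generation probability, so the
#' empirical relation between pgen and population incidence matches the
#' model. Carrying repertoires are chosen uniformly without replacement
#' (keeping the sequence's original repertoire as one carrier); each new
#' placement replaces one random private sequence of the receiving
#' repertoire, so per-repertoire depth is preserved exactly.
#'
#' @param config A [sim_config()].
#' @param engine A generative engine (used when `baseline` is not supplied).
#' @param public_model The public-component [incidence_model()].
#' @param baseline Optional pre-generated baseline `repertoire_dataset`;
#'   generated from `config` and `engine` when `NULL`.
#' @param seed Top-level seed (defaults to `config$seed`).
#' @return A `repertoire_dataset` with realistic public sharing.
#' @export
correct_public_component <- function(config, engine, public_model,
                                     baseline = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(public_model, "incidence_model"))
  if (is.null(baseline)) baseline <- generate_baseline(config, engine, seed)
  if (config$public_fraction == 0) return(baseline)
  rec <- baseline$receptors
  ids <- baseline$metadata$repertoire_id
  n <- config$n_repertoires
  with_stage_seed(seed, "public-correction", {
    keys <- receptor_key(rec)
    first <- !duplicated(keys)
    uniq <- rec[first, ]
    ukeys <- keys[first]
    # each extra placement of a public sequence replaces (and so removes) a
    # private sequence; size the selection against the post-replacement
    # unique count so the realized public share of the final dataset matches
    # public_fraction: m = f * U / (1 + f * (mu - 1)), mu the mean incidence
    # count under the model
    n_probe <- round_half_up(config$public_fraction * nrow(uniq))
    pick <- sample.int(nrow(uniq), n_probe)
    counts_probe <- sample_incidence_count(public_model, uniq$pgen[pick], n)
    mu <- mean(counts_probe)
    m <- if (config$public_fraction == 1) {
      # literal semantics: every unique sequence becomes public; with no
      # private slots left, placements extend the repertoires
      nrow(uniq)
    } else {
      min(n_probe,
          round_half_up(config$public_fraction * nrow(uniq) /
                          (1 + config$public_fraction * (mu - 1))))
    }
    pick <- pick[seq_len(m)]
    pub <- uniq[pick, ]
    pub_keys <- ukeys[pick]
    counts <- counts_probe[seq_len(m)]
    # existing carriers of each chosen sequence (usually exactly one)
    in_pub <- keys %in% pub_keys
    carrier_map <- split(rec$repertoire_id[in_pub], keys[in_pub])
    carriers <- lapply(seq_len(nrow(pub)), function(i) {
      have <- carrier_map[[pub_keys[i]]]
      need <- counts[i] - length(have)
      if (need <= 0) return(character(0))
      sample(setdiff(ids, have), need)
    })
    additions <- build_additions(pub, carriers)
    rec2 <- apply_replacements(rec, additions, protected_keys = pub_keys)
    pr <- baseline$provenance
    pr$stages <- c(pr$stages, "public_correction")
    pr$public_keys <- pub_keys
    new_repertoire_dataset(rec2, baseline$metadata, baseline$manifest, pr)
  })
}

# allocate per-sequence implantation counts: first pass draws from the
# signal model; later single-unit top-ups (still below each cap) close any
# gap so that feasible configurations reach the required total within +/-5%
allocate_signal_counts <- function(drawn, caps, required_total) {
  targets <- pmin(drawn, caps)
  total <- cumsum(targets)
  # trim the pass once the budget is met
  over <- which(total >= required_total)
  if (length(over) > 0) {
    k <- over[1]
    if (k < length(targets)) targets[(k + 1):length(targets)] <- 0
    excess <- total[k] - required_total
    if (targets[k] - excess >= 2) targets[k] <- targets[k] - excess
  }
  # top up toward the budget (caps permitting)
  gap <- required_total - sum(targets)
  while (gap > 0 && any(targets > 0 & targets < caps)) {
    open <- which(targets > 0 & targets < caps)
    add <- pmin(caps[open] - targets[open], ceiling(gap / length(open)))
    add <- pmin(add, pmax(gap - c(0, cumsum(add))[seq_along(add)], 0))
    if (sum(add) == 0) break
    targets[open] <- targets[open] + add
    gap <- required_total - sum(targets)
  }
  # bring unused pool sequences in if still short
  while (gap >= 2 && any(targets == 0 & caps >= 2)) {
    i <- which(targets == 0 & caps >= 2)[1]
    targets[i] <- min(caps[i], max(gap, 2))
    gap <- required_total - sum(targets)
  }
  as.integer(targets)
}

#' Implant signal sequences into positive repertoires
#'
#' Stage iv: labels `round(positive_fraction * n)` repertoires positive,
#' draws signal sequences uniformly without replacement from the pool, gives
#' each an incidence count from the signal incidence model (denominator per
#' `config$signal_denominator`), and places each sequence into that many
#' distinct positive repertoires chosen uniformly, replacing private slots.
#' Drawing continues (topping counts up within each sequence's feasibility
#' cap) until the total implanted instances reach the required total within
#' +/-5% or all caps are exhausted. Negative repertoires receive no implants
#' and are not screened for carrying signal sequences by chance.
#'
#' @param dataset A `repertoire_dataset` (typically the stage-iii output).
#' @param signal_pool Receptor tibble with pgen.
#' @param config A [sim_config()].
#' @param signal_model The signal-component [incidence_model()].
#' @param seed Top-level seed (defaults to `config$seed`).
#' @param override_feasibility Proceed despite an infeasible report
#'   (loudly warned; the realized witness rate will fall short).
#' @return A labeled `repertoire_dataset` whose manifest records every
#'   (signal sequence, repertoire) placement.
#' @export
implant_signals <- function(dataset, signal_pool, config, signal_model,
                            seed = config$seed, override_feasibility = FALSE) {
  stopifnot(inherits(dataset, "repertoire_dataset"),
            inherits(config, "sim_config"))
  signal_pool <- validate_receptors(signal_pool)
  report <- assess_feasibility(signal_pool, config, signal_model)
  if (!report$feasible) {
    if (!override_feasibility) {
      abort(paste0("infeasible witness rate: ", report$guidance),
            class = "pubsim_feasibility_error",
            report = report)
    }
    warn(paste0("proceeding despite infeasibility (override): ",
                report$guidance))
  }
  if (!is.null(config$n_signal_pool_used)) {
    signal_pool <- head(signal_pool, config$n_signal_pool_used)
  }
  ids <- dataset$metadata$repertoire_id
  with_stage_seed(seed, "implant", {
    pos_ids <- sample(ids, config$n_positive)
    metadata <- mutate(dataset$metadata,
                       label = ifelse(.data$repertoire_id %in% pos_ids,
                                      "positive", "negative"))
    required_total <- report$required_total
    if (required_total == 0 || nrow(signal_pool) == 0) {
      pr <- dataset$provenance
      pr$stages <- c(pr$stages, "implant")
      new_repertoire_dataset(dataset$receptors, metadata, NULL, pr)
    } else {
      ord <- sample.int(nrow(signal_pool))
      pool <- signal_pool[ord, ]
      caps <- report$per_sequence_caps$cap[ord]
      denom <- if (config$signal_denominator == "positive") {
        config$n_positive
      } else {
        config$n_repertoires
      }
      drawn <- integer(nrow(pool))
      ok <- pool$pgen > 0
      if (any(ok)) {
        drawn[ok] <- sample_incidence_count(signal_model, pool$pgen[ok], denom)
      }
      targets <- allocate_signal_counts(drawn, caps, required_total)
      keep <- targets > 0
      pool <- pool[keep, ]
      targets <- targets[keep]
      rec <- dataset$receptors
      rec_keys <- receptor_key(rec)
      pool_keys <- receptor_key(pool)
      in_pool <- rec_keys %in% pool_keys
      present_map <- split(rec$repertoire_id[in_pool], rec_keys[in_pool])
      carriers <- lapply(seq_len(nrow(pool)), function(i) {
        # avoid placing into a repertoire already carrying the sequence by
        # chance (set semantics: a duplicate placement would be a no-op)
        present <- present_map[[pool_keys[i]]]
        candidates <- setdiff(pos_ids, present)
        k <- min(targets[i], length(candidates))
        if (k < targets[i]) {
          inform(paste0("signal sequence ", pool$junction_aa[i],
                        " already present by chance; placements reduced by ",
                        targets[i] - k))
        }
        if (k == 0) character(0) else sample(candidates, k)
      })
      additions <- build_additions(pool, carriers)
      protected <- unique(c(pool_keys,
                            dataset$provenance$public_keys %||% character()))
      rec2 <- apply_replacements(rec, additions, protected_keys = protected)
      pr <- dataset$provenance
      pr$stages <- c(pr$stages, "implant")
      new_repertoire_dataset(
        rec2, metadata,
        manifest = additions[, c("junction_aa", "v_call", "j_call",
                                 "repertoire_id")],
        provenance = pr
      )
    }
  })
}

#' Naive signal implantation (no incidence correction)
#'
#' The shortcut-prone construction used by naive simulation approaches:
#' labels are assigned exactly as in [implant_signals()], but every positive
#' repertoire simply receives `round(witness_rate)` signal sequences drawn
#' uniformly from the pool, ignoring the incidence models entirely. Useful
#' for quantifying the generation-probability discordance bias by contrast
#' with the corrected construction.
#'
#' @inheritParams implant_signals
#' @return A labeled `repertoire_dataset` with manifest.
#' @export
implant_signals_naive <- function(dataset, signal_pool, config,
                                  seed = config$seed) {
  stopifnot(inherits(dataset, "repertoire_dataset"))
  signal_pool <- validate_receptors(signal_pool)
  if (!is.null(config$n_signal_pool_used)) {
    signal_pool <- head(signal_pool, config$n_signal_pool_used)
  }
  ids <- dataset$metadata$repertoire_id
  with_stage_seed(seed, "implant", {
    pos_ids <- sample(ids, config$n_positive)
    metadata <- mutate(dataset$metadata,
                       label = ifelse(.data$repertoire_id %in% pos_ids,
                                      "positive", "negative"))
    w <- min(round_half_up(config$witness_rate), nrow(signal_pool))
    if (w == 0 || nrow(signal_pool) == 0) {
      pr <- dataset$provenance
      pr$stages <- c(pr$stages, "implant_naive")
      new_repertoire_dataset(dataset$receptors, metadata, NULL, pr)
    } else {
      take <- lapply(pos_ids, function(rid) sample.int(nrow(signal_pool), w))
      idx <- unlist(take)
      additions <- tibble(
        repertoire_id = rep(pos_ids, each = w),
        junction_aa = signal_pool$junction_aa[idx],
        v_call = signal_pool$v_call[idx],
        j_call = signal_pool$j_call[idx],
        pgen = signal_pool$pgen[idx]
      )
      # drop placements where the repertoire already carries the sequence
      # by chance (set semantics)
      rec <- dataset$receptors
      existing <- paste(rec$repertoire_id, receptor_key(rec))
      dup <- paste(additions$repertoire_id, receptor_key(additions)) %in% existing
      if (any(dup)) {
        inform(paste0(sum(dup), " naive placement(s) were already present ",
                      "by chance and were skipped"))
        additions <- additions[!dup, ]
      }
      pool_keys <- unique(receptor_key(signal_pool))
      rec2 <- apply_replacements(rec, additions,
                                 protected_keys = pool_keys)
      pr <- dataset$provenance
      pr$stages <- c(pr$stages, "implant_naive")
      new_repertoire_dataset(
        rec2, metadata,
        manifest = additions[, c("junction_aa", "v_call", "j_call",
                                 "repertoire_id")],
        provenance = pr
      )
    }
  })
}
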