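#' Probability of observing a receptor at least once in a repertoire
#'
#' Given a receptor's generation probability and the (average unique) number
#' of sequences per repertoire as the number of trials, returns
#' `P(at least one success) = 1 - (1 - pgen)^n_trials`, evaluated as
#' `-expm1(n_trials * log1p(-pgen))` so that tiny `pgen * n_trials` products
#' do not lose precision to cancellation.
#'
#' @param pgen Generation probabilities in `[0, 1]` (vectorized).
#' @param n_trials Number of Bernoulli trials (>= 1).
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' prob_observed_in_repertoire(1e-6, 1e5)
prob_observed_in_repertoire <- function(pgen, n_trials) {
  if (any(pgen < 0 | pgen > 1) || any(n_trials < 1)) {
    abort("pgen must lie in [0, 1] and n_trials must be >= 1",
          class = "pubsim_validation_error")
  }
  out <- -expm1(n_trials * log1p(-pgen))
  out[pgen == 1] <- 1
  out
}

#' Binomial tail probability of a sequence's sharing level
#'
#' `P(X >= observed_count)` for `X ~ Binomial(n_repertoires, p_obs)`: the
#' probability of observing a public sequence in the same or a higher number
#' of repertoires than it was observed in, under convergent recombination
#' alone. Exact survival function, deterministic.
#'
#' @param p_obs Per-repertoire observation probabilities in `[0, 1]`.
#' @param n_repertoires Number of repertoires in the denominator cohort.
#' @param observed_count Observed repertoire counts (`0 <= count <= n`).
#' @param log10_p If `TRUE`, return log10 of the tail probability (computed
#'   in log space; survives tails far below the double underflow threshold).
#' @return Probabilities (or their log10 values).
#' @export
outlier_tail_prob <- function(p_obs, n_repertoires, observed_count,
                              log10_p = FALSE) {
  if (any(p_obs < 0 | p_obs > 1)) {
    abort("p_obs must lie in [0, 1]", class = "pubsim_validation_error")
  }
  if (any(observed_count < 0) || any(observed_count > n_repertoires)) {
    abort("observed_count must lie in [0, n_repertoires]",
          class = "pubsim_validation_error")
  }
  lp <- stats::pbinom(observed_count - 1, n_repertoires, p_obs,
                      lower.tail = FALSE, log.p = TRUE)
  lp[observed_count == 0] <- 0
  if (log10_p) lp / log(10) else exp(lp)
}

#' Outlier score of a public sequence
#'
#' The negative log10 of the binomial tail probability `p_count`. Scores for
#' tails that underflow double precision should be computed from the
#' log-space tail ([outlier_tail_prob()] with `log10_p = TRUE`) rather than
#' from the underflowed probability.
#'
#' @param p_count Tail probabilities in `(0, 1]`.
#' @return Non-negative scores (`-log10(p_count)`).
#' @export
outlier_score <- function(p_count) {
  if (any(p_count > 1)) {
    abort("p_count must be <= 1", class = "pubsim_validation_error")
  }
  -log10(p_count)
}

#' Likelihood ratio of incidence between immune states
#'
#' `LR = (c_P / P) / (c_N / N)`: the ratio of a sequence's empirical
#' incidence rate in positive-class repertoires to its rate in negatives.
#' By convention `c_N = 0` with `c_P > 0` yields `Inf` and `c_P = 0` yields
#' 0; with `pseudocount = TRUE`, 0.5 is added to both occurrence counts.
#'
#' @param c_P,c_N Occurrence counts in positive / negative repertoires.
#' @param P,N Positive / negative repertoire totals (> 0).
#' @param pseudocount Add 0.5 to both counts (keeps ratios finite).
#' @return Non-negative ratios, possibly `Inf`.
#' @export
#' @examples
#' likelihood_ratio(30, 300, 5, 300)
likelihood_ratio <- function(c_P, P, c_N, N, pseudocount = FALSE) {
  if (any(P <= 0) || any(N <= 0)) {
    abort("P and N must be positive", class = "pubsim_validation_error")
  }
  if (any(c_P < 0 | c_P > P) || any(c_N < 0 | c_N > N)) {
    abort("counts must lie in [0, P] / [0, N]",
          class = "pubsim_validation_error")
  }
  if (pseudocount) {
    c_P <- c_P + 0.5
    c_N <- c_N + 0.5
  }
  out <- (c_P / P) / (c_N / N)
  out[c_P == 0] <- 0
  out
}

#' Audit the public sequences of a labeled repertoire dataset
#'
#' Computes, for every public sequence (carried by at least two repertoires,
#' counted irrespective of the immune-state label), its occurrence counts by
#' class, the per-repertoire observation probability `p_obs`, the binomial
#' tail probability `p_count`, the outlier score and the likelihood ratio.
#' The number of trials is the arithmetic mean of unique receptor counts
#' across repertoires, rounded to the nearest integer; the binomial
#' denominator is by default the positive-class repertoire count. When a
#' sequence's total count exceeds the denominator, the tail is evaluated at
#' the denominator (the distribution's upper support).
#'
#' @param dataset A `repertoire_dataset` (see [generate_baseline()]) with
#'   binary labels.
#' @param pgen_of Optional function `(receptor tibble) -> numeric` or engine
#'   used to fill missing pgen values; by default the dataset's stored pgen
#'   column is used and missing values are an error.
#' @param positive_label Label value treated as positive (default
#'   `"positive"`).
#' @param denominator `"positive"` (paper-faithful default) or `"total"`:
#'   which repertoire count the binomial tail is computed against.
#' @return A tibble of class `pubsim_audit`, one row per public sequence,
#'   with attributes `n_trials`, `n_denominator`, `n_positive`, `n_negative`.
#' @export
audit_dataset <- function(dataset, pgen_of = NULL, positive_label = "positive",
                          denominator = c("positive", "total")) {
  stopifnot(inherits(dataset, "repertoire_dataset"))
  denominator <- match.arg(denominator)
  rec <- dataset$receptors
  meta <- dataset$metadata
  if (!all(meta$label %in% c("positive", "negative"))) {
    abort("labels must be binary positive/negative",
          class = "pubsim_validation_error")
  }
  pos_ids <- meta$repertoire_id[meta$label == positive_label]
  n_pos <- length(pos_ids)
  n_neg <- nrow(meta) - n_pos
  n_trials <- round_half_up(mean(dplyr::count(rec, .data$repertoire_id)$n))

  keys <- receptor_key(rec)
  pos_flag <- rec$repertoire_id %in% pos_ids
  cp <- rowsum(as.integer(pos_flag), keys)
  ct <- rowsum(rep(1L, length(keys)), keys)
  first_idx <- match(rownames(ct), keys)
  shared <- tibble(
    .key = rownames(ct),
    junction_aa = rec$junction_aa[first_idx],
    v_call = rec$v_call[first_idx],
    j_call = rec$j_call[first_idx],
    pgen = rec$pgen[first_idx],
    count_positive = as.integer(cp[, 1]),
    count_negative = as.integer(ct[, 1] - cp[, 1]),
    count_total = as.integer(ct[, 1])
  ) |>
    filter(.data$count_total >= 2)
  if (nrow(shared) == 0) {
    out <- tibble(junction_aa = character(), v_call = character(),
                  j_call = character(), pgen = double(),
                  count_positive = integer(), count_negative = integer(),
                  count_total = integer(), p_obs = double(),
                  p_count = double(), outlier_score = double(),
                  likelihood_ratio = double())
    return(new_audit(out, n_trials, 0L, n_pos, n_neg))
  }
  if (!is.null(pgen_of)) {
    fill <- is.na(shared$pgen)
    if (any(fill)) {
      shared$pgen[fill] <- if (inherits(pgen_of, "pubsim_engine")) {
        engine_pgen(pgen_of, shared[fill, ])
      } else {
        pgen_of(shared[fill, ])
      }
    }
  }
  if (anyNA(shared$pgen)) {
    offenders <- shared$junction_aa[is.na(shared$pgen)]
    abort(paste0("public sequences missing a pgen: ",
                 paste(head(offenders, 10), collapse = ", "),
                 if (length(offenders) > 10) " ..." else ""),
          class = "pubsim_validation_error")
  }
  n_denom <- if (denominator == "positive") n_pos else nrow(meta)
  shared <- shared |>
    mutate(
      p_obs = prob_observed_in_repertoire(.data$pgen, n_trials),
      outlier_score = -outlier_tail_prob(
        .data$p_obs, n_denom, pmin(.data$count_total, n_denom),
        log10_p = TRUE
      ),
      p_count = 10^(-.data$outlier_score),
      likelihood_ratio = likelihood_ratio(.data$count_positive, n_pos,
                                          .data$count_negative,
                                          max(n_neg, 1))
    ) |>
    select(-".key") |>
    arrange(dplyr::desc(.data$outlier_score))
  new_audit(shared, n_trials, n_denom, n_pos, n_neg)
}

new_audit <- function(df, n_trials, n_denominator, n_positive, n_negative) {
  structure(as_tibble(df), n_trials = n_trials, n_denominator = n_denominator,
            n_positive = n_positive, n_negative = n_negative,
            class = c("pubsim_audit", class(as_tibble(df))))
}

#' @export
glance.pubsim_audit <- function(x, ...) {
  tibble(
    n_public = nrow(x),
    n_trials = attr(x, "n_trials"),
    n_denominator = attr(x, "n_denominator"),
    n_positive = attr(x, "n_positive"),
    n_negative = attr(x, "n_negative")
  )
}

#' Evaluate an outlier-score decision rule against known signal truth
#'
#' Calls a sequence signal-positive iff its outlier score strictly exceeds
#' the threshold, and scores the rule against a ground-truth identity set.
#' Precision is `TP / (TP + FP)` (0 when there are no calls); recall is
#' `TP / |truth among audited sequences|` (1 by convention when that set is
#' empty, flagged via `truth_audited = 0`).
#'
#' @param records A `pubsim_audit` tibble (or any tibble with
#'   `junction_aa`, `v_call`, `j_call`, `outlier_score`).
#' @param truth Receptor tibble (or key vector) of true signal identities.
#' @param threshold Score threshold; calls use strict `>`.
#' @return One-row tibble: `threshold`, `precision`, `recall`, `tp`, `fp`,
#'   `fn`, `n_calls`, `truth_audited`.
#' @export
threshold_precision_recall <- function(records, truth, threshold) {
  stopifnot(is.finite(threshold))
  keys <- receptor_key(records)
  truth_keys <- if (is.data.frame(truth)) unique(receptor_key(truth)) else unique(truth)
  is_truth <- keys %in% truth_keys
  called <- records$outlier_score > threshold
  tp <- sum(called & is_truth)
  fp <- sum(called & !is_truth)
  fn <- sum(!called & is_truth)
  n_truth <- sum(is_truth)
  tibble(
    threshold = threshold,
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (n_truth == 0) 1 else tp / n_truth,
    tp = tp, fp = fp, fn = fn,
    n_calls = tp + fp,
    truth_audited = n_truth
  )
}

#' @export
autoplot.pubsim_audit <- function(object, truth = NULL, threshold = NULL, ...) {
  d <- as_tibble(object)
  d$is_signal <- if (is.null(truth)) {
    FALSE
  } else {
    receptor_key(d) %in% unique(receptor_key(truth))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$pgen),
                                       y = .data$outlier_score,
                                       colour = .data$is_signal)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 name = "true signal") +
    ggplot2::labs(x = "log10 generation probability", y = "outlier score") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Write an audit to disk
#'
#' One TSV row per public sequence plus a JSON summary with the audit header
#' (n_trials, denominators) and precision/recall at the requested thresholds.
#'
#' @param audit A `pubsim_audit`.
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @param truth Optional truth set for the JSON summary.
#' @param thresholds Numeric thresholds evaluated in the summary.
#' @return The audit, invisibly.
#' @export
write_audit <- function(audit, path_tsv, path_json = NULL, truth = NULL,
                        thresholds = 35) {
  readr::write_tsv(as_tibble(audit), path_tsv)
  if (!is.null(path_json)) {
    summary <- as.list(glance(audit))
    if (!is.null(truth)) {
      summary$rules <- lapply(thresholds, function(t) {
        as.list(threshold_precision_recall(audit, truth, t))
      })
    }
    jsonlite::write_json(summary, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(audit)
}
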