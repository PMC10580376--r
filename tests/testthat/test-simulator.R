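test_that("feasibility arithmetic matches the worked example", {
  models <- synthetic_incidence_models()
  cfg <- sim_config(n_repertoires = 200, positive_fraction = 0.5,
                    depth = 1000, witness_rate = 5, seed = 1)
  pool3 <- receptor_tbl(c("CASSLWKDYEQYF", "CASSYREVTEQYF", "CASSERFYNEQFF"),
                        "TRBV1", "TRBJ1", pgen = c(1e-7, 1e-9, 1e-11))
  rep3 <- assess_feasibility(pool3, cfg, models$signal)
  # 100 positives x witness 5 = 500 required; 3 x floor(200 x 0.3) = 180
  expect_equal(rep3$required_total, 500L)
  expect_equal(rep3$achievable_total, 180L)
  expect_false(rep3$feasible)
  expect_equal(tidy(rep3)$cap, rep(60L, 3))
  expect_match(rep3$guidance, "infeasible")

  pool10 <- receptor_tbl(paste0("CASS", c("A", "C", "D", "E", "F", "G", "H",
                                          "I", "K", "L"), "WEQYF"),
                         "TRBV1", "TRBJ1", pgen = 1e-9)
  rep10 <- assess_feasibility(pool10, cfg, models$signal)
  expect_equal(rep10$achievable_total, 600L)
  expect_true(rep10$feasible)

  # zero witness rate is vacuously feasible
  cfg0 <- sim_config(n_repertoires = 200, positive_fraction = 0.5,
                     depth = 1000, witness_rate = 0, seed = 1)
  rep0 <- assess_feasibility(pool3, cfg0, models$signal)
  expect_equal(rep0$required_total, 0L)
  expect_true(rep0$feasible)
})

test_that("baseline generation honors counts, uniqueness and seeds", {
  engine <- toy_trb()
  cfg <- sim_config(n_repertoires = 3, positive_fraction = 0.5, depth = 10,
                    seed = 5)
  ds <- generate_baseline(cfg, engine)
  expect_equal(nrow(ds$metadata), 3)
  per_rep <- dplyr::count(ds$receptors, repertoire_id)
  expect_equal(per_rep$n, rep(10L, 3))
  # unique within each repertoire
  expect_false(any(duplicated(
    paste(ds$receptors$repertoire_id, receptor_key(ds$receptors)))))
  # byte-for-byte determinism under the seed
  ds2 <- generate_baseline(cfg, engine)
  expect_identical(ds, ds2)
  expect_false(identical(ds, generate_baseline(cfg, engine, seed = 6)))

  # depth spread: targets stay inside the band
  cfgs <- sim_config(n_repertoires = 12, positive_fraction = 0.5,
                     depth = 100, depth_spread = 10, seed = 2)
  dss <- generate_baseline(cfgs, engine)
  depths <- dplyr::count(dss$receptors, repertoire_id)$n
  expect_true(all(depths >= 90 & depths <= 110))
  expect_gt(length(unique(depths)), 1)
})

test_that("public correction is a no-op at fraction 0 and exact for point masses", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  cfg0 <- sim_config(n_repertoires = 10, positive_fraction = 0.5, depth = 50,
                     public_fraction = 0, seed = 3)
  base <- generate_baseline(cfg0, engine)
  expect_identical(correct_public_component(cfg0, engine, models$public,
                                            baseline = base),
                   base)

  # public_fraction 1 with a point-mass model at fraction ~0.5: every unique
  # sequence is carried by exactly round(0.5 x 10) = 5 repertoires
  pm <- incidence_model(pgen_binning(c(-Inf, 0)),
                        incidence_binning(c(0, 0.5, 0.5 + 1e-9, 1)),
                        matrix(c(0, 1, 0), 1), 10L, "public")
  cfg1 <- sim_config(n_repertoires = 10, positive_fraction = 0.5, depth = 50,
                     public_fraction = 1, seed = 4)
  ds <- correct_public_component(cfg1, engine, pm)
  occ <- dataset_occurrences(ds)
  expect_true(all(occ$count == 5))
  # all surviving unique sequences are public (share 1)
  expect_equal(realized_public_share(ds), 1)
})

test_that("public correction hits the configured share and respects caps", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  cfg <- sim_config(n_repertoires = 50, positive_fraction = 0.5, depth = 500,
                    public_fraction = 0.10, seed = 7)
  ds <- correct_public_component(cfg, engine, models$public)
  share <- realized_public_share(ds)
  expect_lt(abs(share - 0.10), 0.01)
  occ <- dataset_occurrences(ds)
  caps <- floor(max_incidence_fraction(models$public, occ$pgen) * 50)
  expect_true(all(occ$count >= 2))
  expect_true(all(occ$count <= pmax(caps, 2)))
  # depth conserved
  expect_equal(dplyr::count(ds$receptors, repertoire_id)$n, rep(500L, 50))
})

test_that("signal implantation meets forced and budgeted allocations", {
  engine <- toy_trb()
  # forced allocation: 1 sequence, point mass at fraction 1, witness 1
  pm <- incidence_model(pgen_binning(c(-Inf, 0)),
                        incidence_binning(c(0, 1 - 1e-9, 1)),
                        matrix(c(0, 1), 1), 10L, "signal")
  cfg <- sim_config(n_repertoires = 20, positive_fraction = 0.5, depth = 100,
                    public_fraction = 0, witness_rate = 1, seed = 8)
  base <- generate_baseline(cfg, engine)
  pool1 <- receptor_tbl("CASSWKDYAEQYF", "TRBV1", "TRBJ1", pgen = 1e-8)
  ds <- implant_signals(base, pool1, cfg, pm)
  expect_equal(nrow(ds$manifest), 10)
  pos <- ds$metadata$repertoire_id[ds$metadata$label == "positive"]
  expect_setequal(ds$manifest$repertoire_id, pos)
  # the sequence is actually present in every positive repertoire
  carried <- ds$receptors$repertoire_id[
    ds$receptors$junction_aa == "CASSWKDYAEQYF"]
  expect_setequal(carried, pos)

  # witness 0: labels assigned, empty manifest
  cfg0 <- sim_config(n_repertoires = 20, positive_fraction = 0.5, depth = 100,
                     witness_rate = 0, seed = 8)
  ds0 <- implant_signals(base, pool1, cfg0, pm)
  expect_equal(nrow(ds0$manifest), 0)
  expect_setequal(ds0$metadata$label, c("positive", "negative"))
  expect_equal(sum(ds0$metadata$label == "positive"), 10)
})

test_that("infeasible configs error with the report unless overridden", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  cfg <- sim_config(n_repertoires = 20, positive_fraction = 0.5, depth = 100,
                    public_fraction = 0, witness_rate = 10, seed = 9)
  base <- generate_baseline(cfg, engine)
  pool <- receptor_tbl("CASSWKDYAEQYF", "TRBV1", "TRBJ1", pgen = 1e-8)
  err <- expect_error(implant_signals(base, pool, cfg, models$signal),
                      class = "pubsim_feasibility_error")
  expect_s3_class(err$report, "feasibility_report")
  expect_warning(
    ds <- implant_signals(base, pool, cfg, models$signal,
                          override_feasibility = TRUE),
    "override"
  )
  expect_lt(nrow(ds$manifest), err$report$required_total)
})

test_that("feasible configurations reach the required total within 5%", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  pool <- make_signal_pool(engine, n = 12, seed = 21)
  for (seed in 1:10) {
    cfg <- sim_config(n_repertoires = 40, positive_fraction = 0.5,
                      depth = 400, public_fraction = 0, witness_rate = 3,
                      seed = seed)
    base <- generate_baseline(cfg, engine)
    rep <- assess_feasibility(pool, cfg, models$signal)
    expect_true(rep$feasible)
    ds <- implant_signals(base, pool, cfg, models$signal)
    expect_gte(nrow(ds$manifest), ceiling(rep$required_total * 0.95))
    expect_lte(nrow(ds$manifest), floor(rep$required_total * 1.05))
    # no sequence exceeds its cap, and all manifest targets are positive
    man <- dplyr::count(ds$manifest, junction_aa, v_call, j_call)
    caps <- tidy(rep)
    joined <- dplyr::inner_join(man, caps,
                                by = c("junction_aa", "v_call", "j_call"))
    expect_true(all(joined$n <= joined$cap))
    pos <- ds$metadata$repertoire_id[ds$metadata$label == "positive"]
    expect_true(all(ds$manifest$repertoire_id %in% pos))
  }
})

test_that("full pipeline is reproducible and conserves depth end to end", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  pool <- make_signal_pool(engine, n = 10, seed = 31)
  cfg <- sim_config(n_repertoires = 30, positive_fraction = 0.5, depth = 300,
                    public_fraction = 0.1, witness_rate = 2, seed = 13)
  run <- function() {
    ds <- correct_public_component(cfg, engine, models$public)
    implant_signals(ds, pool, cfg, models$signal)
  }
  a <- run()
  b <- run()
  expect_identical(a$receptors, b$receptors)
  expect_identical(a$manifest, b$manifest)
  expect_equal(dplyr::count(a$receptors, repertoire_id)$n, rep(300L, 30))
  # manifest placements all exist in the receptor table
  man_keys <- paste(a$manifest$repertoire_id, receptor_key(a$manifest))
  rec_keys <- paste(a$receptors$repertoire_id, receptor_key(a$receptors))
  expect_true(all(man_keys %in% rec_keys))
})

test_that("recalibration recovers the generating incidence model", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  # cohort large enough that the minimum public count 2 maps into the
  # lowest incidence bin (2/300 < 0.02)
  cfg <- sim_config(n_repertoires = 300, positive_fraction = 0.5,
                    depth = 600, public_fraction = 0.10, seed = 17)
  ds <- correct_public_component(cfg, engine, models$public)
  occ <- dataset_occurrences(ds)
  recal <- calibrate_incidence(occ, total_repertoires = 300)
  tv_ok <- TRUE
  for (r in seq_len(4)) {
    if (recal$public$row_counts[r] >= 500) {
      tv <- 0.5 * sum(abs(recal$public$table[r, ] - models$public$table[r, ]))
      tv_ok <- tv_ok && (tv < 0.05)
    }
  }
  expect_gte(sum(recal$public$row_counts >= 500), 2)
  expect_true(tv_ok)
})

test_that("smaller cohorts inflate the learned incidence fractions", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  cfg <- sim_config(n_repertoires = 150, positive_fraction = 0.5,
                    depth = 500, public_fraction = 0.10, seed = 19)
  ds <- correct_public_component(cfg, engine, models$public)
  mean_frac <- function(receptors, rep_ids) {
    keep <- receptors$repertoire_id %in% rep_ids
    sub <- receptors[keep, ]
    keys <- receptor_key(sub)
    ct <- rowsum(rep(1L, length(keys)), keys)[, 1]
    mean(ct[ct >= 2] / length(rep_ids))
  }
  all_ids <- ds$metadata$repertoire_id
  withr::with_seed(1, sub_ids <- sample(all_ids, 50))
  expect_gt(mean_frac(ds$receptors, sub_ids),
            mean_frac(ds$receptors, all_ids))
})

test_that("monotone support: higher counts never map to lower incidence bins", {
  ib <- incidence_binning()
  for (n in c(50, 200, 1000)) {
    counts <- 2:n
    bins <- pubsim:::bin_index(counts / n, ib$edges)
    expect_true(all(diff(bins) >= 0))
  }
})

test_that("corrected sharing creates outliers only as the model dictates", {
  engine <- toy_trb()
  models <- synthetic_incidence_models()
  n <- 50
  cfg <- sim_config(n_repertoires = n, positive_fraction = 0.5, depth = 2000,
                    public_fraction = 0.10, witness_rate = 0, seed = 47)
  ds <- correct_public_component(cfg, engine, models$public)
  ds <- implant_signals(ds, receptor_tbl("CASSWKDYAEQYF", "TRBV1", "TRBJ1",
                                         pgen = 1e-8),
                        cfg, models$signal)
  audit <- audit_dataset(ds)
  n_pos <- attr(audit, "n_denominator")
  n_trials <- attr(audit, "n_trials")
  threshold <- 35

  # expected number of rule calls among the model-drawn public sequences:
  # for each selected sequence, the model row gives the distribution of its
  # repertoire count (uniform fraction within the drawn bin, floored), and
  # the binomial tail fixes the minimal count k* that scores above the
  # threshold
  pub_keys <- ds$provenance$public_keys
  audited_pub <- audit[pubsim:::receptor_key(audit) %in% pub_keys, ]
  edges <- models$public$incidence_binning$edges
  p_call <- vapply(seq_len(nrow(audited_pub)), function(i) {
    pgen <- audited_pub$pgen[i]
    p_obs <- prob_observed_in_repertoire(pgen, n_trials)
    scores <- -outlier_tail_prob(p_obs, n_pos, 0:n_pos, log10_p = TRUE)
    k_star <- which(scores > threshold)[1] - 1
    if (is.na(k_star)) return(0)
    row <- models$public$table[pubsim:::pgen_bin_of(models$public$pgen_binning,
                                                    pgen), ]
    p <- 0
    for (j in seq_along(row)) {
      if (row[j] == 0) next
      l <- edges[j]; r <- edges[j + 1]
      frac_needed <- k_star / n
      p <- p + row[j] * min(max((r - max(frac_needed, l)) / (r - l), 0), 1)
    }
    p
  }, numeric(1))
  expected <- sum(p_call)
  sd3 <- 3 * sqrt(sum(p_call * (1 - p_call)))
  truth_keys <- unique(pubsim:::receptor_key(ds$manifest))
  realized <- sum(audit$outlier_score > threshold &
                    !(pubsim:::receptor_key(audit) %in% truth_keys))
  expect_gt(expected, 5)  # the regime actually produces outliers
  expect_lt(abs(realized - expected), sd3 + 3)
})
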