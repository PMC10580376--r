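test_that("binnings use half-open intervals with clamping", {
  pb <- pgen_binning(c(-Inf, -12, -9, -6, 0))
  expect_equal(pubsim:::pgen_bin_of(pb, 1e-13), 1)
  expect_equal(pubsim:::pgen_bin_of(pb, 1e-12), 2)  # left endpoint included
  expect_equal(pubsim:::pgen_bin_of(pb, 1e-9), 3)
  expect_equal(pubsim:::pgen_bin_of(pb, 0.5), 4)    # clamped into last bin
  ib <- incidence_binning()
  expect_equal(pubsim:::bin_index(0.02, ib$edges), 2)
  expect_equal(pubsim:::bin_index(0.0199, ib$edges), 1)
  expect_equal(pubsim:::bin_index(1, ib$edges), 6)
  expect_error(pgen_binning(c(-3, -3)), class = "pubsim_config_error")
})

test_that("calibration tallies hand-built data into the right cells", {
  # 10 public sequences, one pgen bin, all seen in 2 of 200 repertoires:
  # a single point-mass cell in [0, 0.02)
  aa10 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  occ <- receptor_tbl(paste0("CASS", aa10, "F"), "V1", "J1",
                      pgen = 1e-7)
  occ$count <- 2L
  m <- calibrate_incidence(occ, total_repertoires = 200)
  expect_equal(sum(m$public$row_counts), 10)
  expect_equal(m$public$table[3, 1], 1)  # log10(1e-7) -> bin 3, frac 0.01
  expect_equal(sum(m$public$table), 1)
  # empty signal set leaves the signal component vacuous
  expect_equal(sum(m$signal$row_counts), 0)

  # 6 sequences spanning 2 pgen bins and 2 incidence bins: manual tally
  occ2 <- receptor_tbl(paste0("CASS", aa10[1:6], "F"), "V1", "J1",
                       pgen = c(1e-7, 1e-7, 1e-7, 1e-10, 1e-10, 1e-10))
  occ2$count <- c(2L, 2L, 30L, 2L, 30L, 30L)  # 30/200 = 0.15 -> incidence bin 4
  m2 <- calibrate_incidence(occ2, total_repertoires = 200)
  # pgen 1e-7 -> pgen bin 3; pgen 1e-10 -> pgen bin 2
  expect_equal(m2$public$table[3, 1], 2 / 3)
  expect_equal(m2$public$table[3, 4], 1 / 3)
  expect_equal(m2$public$table[2, 1], 1 / 3)
  expect_equal(m2$public$table[2, 4], 2 / 3)
})

test_that("signal and public components use their own denominators", {
  occ <- receptor_tbl(c("CASSAF", "CASSGF"), "V1", "J1", pgen = 1e-7)
  occ$count <- c(30L, 30L)
  m <- calibrate_incidence(occ, total_repertoires = 600,
                           positive_repertoires = 300,
                           signal_keys = occ[1, ])
  # signal: 30/300 = 0.10 -> bin [0.1, 0.2); public: 30/600 = 0.05 -> bin 3
  expect_equal(m$signal$table[3, 4], 1)
  expect_equal(m$public$table[3, 3], 1)
})

test_that("calibration rejects counts below 2, missing pgen, duplicates", {
  occ <- receptor_tbl("CASSAF", "V1", "J1", pgen = 1e-7)
  occ$count <- 1L
  expect_error(calibrate_incidence(occ, 100), class = "pubsim_validation_error")
  occ$count <- 2L
  occ$pgen <- NA_real_
  expect_error(calibrate_incidence(occ, 100), class = "pubsim_validation_error")
  occ$pgen <- 1e-7
  occ$count <- 300L
  expect_error(calibrate_incidence(occ, 100), class = "pubsim_validation_error")
})

test_that("incidence counts respect degenerate rows, floors and caps", {
  pb <- pgen_binning(c(-Inf, 0))
  ib <- incidence_binning(c(0, 0.1, 0.1 + 1e-9, 1))
  m <- incidence_model(pb, ib, matrix(c(0, 1, 0), 1), 5L, "public")
  # point mass at fraction ~0.10 with denominator 100 -> always 10
  expect_equal(unique(sample_incidence_count(m, rep(1e-5, 50), 100, seed = 1)),
               10)
  # tiny fractions still give counts >= 2
  m2 <- incidence_model(pb, incidence_binning(c(0, 0.001, 1)),
                        matrix(c(1, 0), 1), 5L, "public")
  cnt <- sample_incidence_count(m2, rep(1e-5, 200), 1000, seed = 2)
  expect_true(all(cnt >= 2))

  # stochastic check: row {0.9 on [0, 0.02), 0.1 on [0.02, 0.1)}: the
  # fraction of counts >= 20 (of 1000) is within 3 SE of 0.1
  m3 <- incidence_model(pb, incidence_binning(c(0, 0.02, 0.1, 1)),
                        matrix(c(0.9, 0.1, 0), 1), 10L, "public")
  cnt3 <- sample_incidence_count(m3, rep(1e-5, 1e4), 1000, seed = 3)
  frac <- mean(cnt3 >= 20)
  # floor(fraction * 1000) >= 20 exactly when the drawn bin is [0.02, 0.1),
  # so the expected rate is the bin mass 0.1 (binomial sampling oracle)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e4))
})

test_that("maximum incidence fraction is the top occupied bin edge", {
  pb <- pgen_binning(c(-Inf, 0))
  expect_equal(
    max_incidence_fraction(
      incidence_model(pb, incidence_binning(c(0, 0.02, 1)),
                      matrix(c(1, 0), 1), 1L, "public"), 1e-5),
    0.02
  )
  expect_equal(
    max_incidence_fraction(
      incidence_model(pb, incidence_binning(c(0, 0.02, 0.2, 0.3, 1)),
                      matrix(c(0.5, 0, 0.5, 0), 1), 1L, "public"), 1e-5),
    0.3
  )
  # the synthetic fixtures cap every pgen bin at 30% of the cohort
  models <- synthetic_incidence_models()
  for (pg in c(1e-13, 1e-10, 1e-7, 1e-3)) {
    expect_equal(max_incidence_fraction(models$signal, pg), 0.3)
  }
})

test_that("empty rows borrow the nearest trained lower-pgen row", {
  pb <- pgen_binning(c(-Inf, -9, -6, 0))
  ib <- incidence_binning(c(0, 0.1, 1))
  tab <- rbind(c(1, 0), c(0, 0), c(0.5, 0.5))
  m <- incidence_model(pb, ib, tab, c(10L, 0L, 10L), "public")
  # bin 2 is empty -> borrows row 1 (max fraction 0.1, not 1)
  expect_equal(max_incidence_fraction(m, 1e-8), 0.1)
  expect_warning(sample_incidence_count(m, 1e-8, 100, seed = 1),
                 "borrowing")
  # a fully untrained model is unusable
  m0 <- incidence_model(pb, ib, matrix(0, 3, 2), rep(0L, 3), "public")
  expect_error(sample_incidence_count(m0, 1e-8, 100, seed = 1),
               class = "pubsim_model_error")
})

test_that("models round-trip through JSON and TSV and reject bad files", {
  models <- synthetic_incidence_models()
  for (ext in c(".json", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_incidence_model(models$public, path)
    m2 <- read_incidence_model(path)
    expect_equal(m2$table, models$public$table)
    expect_equal(m2$pgen_binning$edges, models$public$pgen_binning$edges)
    expect_equal(m2$incidence_binning$edges,
                 models$public$incidence_binning$edges)
    expect_equal(m2$row_counts, models$public$row_counts)
    expect_equal(m2$component_label, "public")
  }
  # a row that does not sum to 1 is refused with its index
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    version = 1, component_label = "public",
    pgen_log10_edges = c(-15, 0), incidence_edges = c(0, 0.5, 1),
    row_counts = 3, rows = list(c(0.5, 0.3))
  ), bad, auto_unbox = TRUE)
  expect_error(read_incidence_model(bad), "row 1")
  # unknown version is refused
  badv <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(version = 99), badv, auto_unbox = TRUE)
  expect_error(read_incidence_model(badv), class = "pubsim_validation_error")
})

test_that("hand-written model file loads to its own matrix", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "version": 1, "component_label": "signal",
    "pgen_log10_edges": [-15, -8, 0],
    "incidence_edges": [0, 0.5, 1],
    "row_counts": [4, 6],
    "rows": [[0.25, 0.75], [1, 0]]
  }', path)
  m <- read_incidence_model(path)
  expect_equal(m$table, rbind(c(0.25, 0.75), c(1, 0)))
  expect_equal(m$row_counts, c(4L, 6L))
})

test_that("tidy and glance expose the binned distribution", {
  m <- synthetic_incidence_models()$signal
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 6)
  expect_equal(sum(td$prob), 4)
  g <- glance(m)
  expect_equal(g$n_train, 4000)
  expect_equal(g$n_empty_rows, 0)
  expect_s3_class(autoplot(m), "ggplot")
})
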