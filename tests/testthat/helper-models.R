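# Toy-model fixtures and independent oracles shared across tests.

# degenerate model: a single generatable receptor with probability 1
toy_single_path <- function() {
  toy_generative_model(
    v_segments = data.frame(id = "V1", prefix = "CASS", prob = 1),
    j_segments = data.frame(id = "J1", suffix = "F", prob = 1),
    junction_length_dist = data.frame(length = 0, prob = 1),
    residue_dist = c(A = 1)
  )
}

# four equiprobable receptors: 2 V x 1 J x middle length 1 over {A, G}
toy_four_receptor <- function() {
  toy_generative_model(
    v_segments = data.frame(id = c("V1", "V2"), prefix = c("CASS", "CASR"),
                            prob = c(0.5, 0.5)),
    j_segments = data.frame(id = "J1", suffix = "F", prob = 1),
    junction_length_dist = data.frame(length = 1, prob = 1),
    residue_dist = c(A = 0.5, G = 0.5)
  )
}

# richer model for simulation tests: the package's packaged TCRbeta-like
# example engine
toy_trb <- function() toy_model_trb()

# signal pool for simulation tests: unique receptors drawn from the engine
# itself, restricted to a mid-range pgen band so every sequence has a
# nonzero, implantable generation probability
make_signal_pool <- function(engine, n = 10, seed = 99,
                             pgen_range = c(1e-11, 1e-8)) {
  pool <- build_reference_pool(engine, 30000, seed)
  pool <- pool[pool$pgen >= pgen_range[1] & pool$pgen <= pgen_range[2], ]
  stopifnot(nrow(pool) >= n)
  pool[seq_len(n), ]
}

# brute-force binomial survival oracle, summed in log space via lchoose so
# it stays meaningful deep into the tail; independent of stats::pbinom
oracle_tail <- function(n, p, k) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  ks <- k:n
  logterms <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  m <- max(logterms)
  exp(m) * sum(exp(logterms - m))
}

# naive character-scan pattern matcher (oracle for match_patterns)
oracle_scan <- function(pool, patterns, mode = "any") {
  hit <- vapply(seq_len(nrow(pool)), function(i) {
    found <- vapply(patterns, function(p) {
      grepl(p, pool$junction_aa[i], fixed = TRUE)
    }, logical(1))
    if (mode == "any") any(found) else all(found)
  }, logical(1))
  pool[hit, ]
}

# measure the realized public share: fraction of the dataset's unique
# sequences observed in >= 2 repertoires
realized_public_share <- function(dataset) {
  occ <- dataset_occurrences(dataset)
  keys <- receptor_key(dataset$receptors)
  nrow(occ) / length(unique(keys))
}
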