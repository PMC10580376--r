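# pubsim

Simulation of adaptive immune receptor repertoire (AIRR) cohorts with
realistic interindividual receptor sharing, for benchmarking immune-state
prediction methods.

## The problem

A labeled AIRR cohort consists of repertoires — sets of receptor sequences
(amino-acid CDR3 junction plus V/J gene calls) sampled from individuals —
with a binary immune-state label. Benchmarks for repertoire classifiers are
usually simulated: baseline repertoires are sampled from a V(D)J
recombination model and "signal" sequences are implanted into the
positive-class repertoires.

Such naive simulation leaves an artifact. In experimental cohorts of
antigen-experienced repertoires, many *public* sequences (those observed in
more than one individual) are shared far more widely than their V(D)J
generation probability (p<sub>gen</sub>) predicts, because individuals
accumulate common immune exposures over a lifetime. In naive simulations the
only sequences whose sharing is inconsistent with p<sub>gen</sub> are the
implanted signals. A classifier can therefore "cheat" by flagging
generation-probability outliers instead of learning the signal — shortcut
learning on a benchmark artifact (*generation probability discordance
bias*).

`pubsim` removes that shortcut. It calibrates, from a labeled cohort, the
empirical distribution of population incidence conditional on
p<sub>gen</sub> — separately for signal and for other public sequences — and
simulates cohorts in which **both** the background public component and the
implanted signals follow those distributions.

## The statistics at its core

For each public sequence with generation probability p<sub>gen</sub>,
observed in *c* of the repertoires:

- p<sub>obs</sub> = 1 − (1 − p<sub>gen</sub>)<sup>n</sup>, the probability of
  observing the sequence at least once in a repertoire of *n* unique
  receptors;
- p<sub>count</sub> = P(X ≥ c) for X ~ Binomial(N, p<sub>obs</sub>) over the
  N positive-class repertoires; the **outlier score** is
  −log₁₀ p<sub>count</sub>, computed in log space so scores of many hundreds
  remain exact;
- the **likelihood ratio** LR = (c_P/P)/(c_N/N) compares incidence rates
  between the positive and negative classes.

The simulation workflow has four stages: (i) *feasibility* — check that a
desired witness rate (mean signal sequences per positive repertoire) is
achievable from the user's signal pool, given the per-sequence incidence
caps the calibrated model implies; (ii) *baseline generation* from a
recombination engine; (iii) *public-component correction* — make a
configurable share (default 10%) of unique sequences public with incidence
counts drawn from the calibrated model; (iv) *signal implantation* under the
signal-component model, with a ground-truth manifest.

A built-in toy recombination engine (`toy_model_trb()`) with exactly
enumerable generation probabilities supports tests and examples; an adapter
(`olga_engine()`) exposes the external OLGA engine behind the same contract
when it is installed.

## Worked example

```r
library(pubsim)

engine <- toy_model_trb()
models <- synthetic_incidence_models()   # synthetic signal/public fixtures

# can a 3-sequence pool support 5 signal sequences per positive repertoire?
config <- sim_config(n_repertoires = 200, positive_fraction = 0.5,
                     depth = 1000, witness_rate = 5, seed = 1)
pool <- receptor_tbl(c("CASSLWKDYEQYF", "CASSYREVTEQYF", "CASSERFYNEQFF"),
                     "TRBV1", "TRBJ1", pgen = c(1e-7, 1e-9, 1e-11))
assess_feasibility(pool, config, models$signal)
#> <feasibility_report>
#>   infeasible: the pool of 3 sequence(s) can contribute at most 180 signal
#>   instances but 500 are required (100 positive repertoires x witness rate 5);
#>   supply a larger pool or lower the witness rate (shortfall: 320 instances)
```

100 positive repertoires × witness rate 5 demand 500 signal instances, but
each sequence is capped at 30% incidence of the 200-repertoire cohort
(3 × 60 = 180), so the request is refused before any expensive simulation
runs. With a feasible pool, the full workflow and the bias audit:

```r
pool <- build_reference_pool(engine, 30000, seed = 99)
pool <- head(pool[pool$pgen > 1e-11 & pool$pgen < 1e-8, ], 10)
config <- sim_config(n_repertoires = 50, positive_fraction = 0.5,
                     depth = 5000, public_fraction = 0.10,
                     witness_rate = 5, seed = 1)

shortcut_bias_experiment(engine, config, pool, models, threshold = 35)
#> # A tibble: 2 x 10
#>   dataset   n_public threshold precision recall    tp    fp    fn n_calls truth_audited
#>   <chr>        <int>     <dbl>     <dbl>  <dbl> <int> <int> <int>   <int>         <int>
#> 1 naive          169        35     1      0.9       9     0     1       9            10
#> 2 corrected    22726        35     0.112  1        10    79     0      89            10
```

On the naively implanted cohort the decision rule "outlier score > 35"
retrieves the implanted signals with perfect precision — the shortcut. On
the incidence-corrected cohort the same rule drowns in background public
sequences whose extreme sharing the incidence model prescribes, so the
shortcut collapses while the signals (and labels) are unchanged.

Other entry points: `audit_dataset()` + `threshold_precision_recall()` for
bias audits of any labeled dataset, `calibrate_incidence()` to learn
incidence models from data, `match_patterns()` to select k-mer-carrying
signal pools from a reference pool without motif implantation,
`run_workflow()` / the `inst/cli/pubsim` script for end-to-end runs, and
`autoplot()` methods for incidence models and audits.

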