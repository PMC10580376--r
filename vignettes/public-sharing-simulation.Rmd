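---
title: "Simulating AIRR cohorts with realistic public sequence sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AIRR cohorts with realistic public sequence sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pubsim)
library(dplyr)
```

## The model

An adaptive immune receptor repertoire (AIRR) is, for our purposes, a set of
unique receptors, each identified by the triple (amino-acid junction, V
call, J call). Across a cohort, a receptor is *public* when it occurs in at
least two repertoires; its *population incidence* is the fraction of
repertoires carrying it. Two mechanisms drive publicness: convergent
recombination (receptors with high generation probability p~gen~ arise
independently in many individuals) and antigen-driven selection (individuals
sharing an immune exposure share responding receptors regardless of
p~gen~).

The quantity the package is organized around is the conditional distribution

$$ P(\text{incidence bin } j \mid \text{p}_{gen} \text{ bin } i), $$

estimated separately for immune-state *signal* sequences and for all other
public sequences — the `incidence_model` pair. Naive simulations implicitly
set this distribution to whatever convergent recombination alone produces,
which makes implanted signals the only incidence outliers and opens a
shortcut for classifiers. Simulating both components from calibrated
distributions closes it.

### Outlier score and likelihood ratio

For a public sequence with generation probability $p$ observed in $c$
repertoires, with $n$ the mean unique-receptor count per repertoire
(rounded) and $N$ the positive-class repertoire count:

* $p_{obs} = 1 - (1-p)^n$, evaluated as `-expm1(n * log1p(-p))` so that
  $p \cdot n \ll 1$ does not cancel;
* $p_{count} = P(X \ge c)$, $X \sim \mathrm{Binom}(N, p_{obs})$ — the exact
  binomial survival function;
* outlier score $= -\log_{10} p_{count}$, evaluated with
  `pbinom(log.p = TRUE)` end to end, so tails far below the double-precision
  underflow threshold (scores of several hundred) stay exact;
* likelihood ratio $LR = (c_P/P)/(c_N/N)$, with $c_N = 0$ giving `Inf` by
  convention and an optional +0.5 pseudocount mode.

Occurrences are counted over all repertoires irrespective of label, while
the binomial denominator is the positive-class count; when a count exceeds
that denominator the tail is evaluated at the denominator (the
distribution's upper support). A `denominator = "total"` option switches
both to the full cohort.

## The workflow stages and their parameters

`sim_config()` carries the user-facing knobs:

| parameter | meaning | default |
|---|---|---|
| `n_repertoires` | cohort size | — |
| `positive_fraction` | share of positive labels | 0.5 |
| `depth`, `depth_spread` | target unique receptors per repertoire, ± band | spread 0 |
| `public_fraction` | share of unique sequences made public | 0.10 |
| `witness_rate` | mean signal sequences per positive repertoire | 0 |
| `signal_denominator` | cohort the signal incidence fractions refer to | `"positive"` |
| `seed` | top-level seed; every stage derives a labelled substream | — |

The witness rate is also reported per $10^5$ receptors
(`witness_rate / depth * 1e5`), the unit natural for deep cohorts.

**(i) Feasibility.** `required_total = round(n_positive * witness_rate)`.
Each pool sequence is capped at
`floor(max_incidence_fraction(signal_model, pgen) * n_repertoires)`
carriers — the cap is taken against the *total* cohort, following the
standard worked arithmetic of this assessment (3 sequences × 200 repertoires
× 0.3 = 180 achievable against 500 required), additionally bounded by the
positive count since implanted carriers are distinct positive repertoires.

**(ii) Baseline.** Each repertoire is an i.i.d. engine sample deduplicated
to its depth target. Sharing at this stage is convergent recombination
only.

**(iii) Public correction.** A `public_fraction` share of unique sequences
is selected; each selected sequence's carrier count is drawn from the
public model conditional on its p~gen~; carriers are chosen uniformly
without replacement (the originating repertoire stays a carrier); each new
placement replaces a random private sequence of the receiving repertoire,
preserving depth exactly. Because each replacement consumes a private
(usually unique) sequence, the selection size is solved as
$m = fU/(1 + f(\mu - 1))$ — $U$ the unique count, $\mu$ the mean drawn
carrier count — so the *realized* public share of the final dataset matches
`public_fraction`. At the degenerate `public_fraction = 1` every unique
sequence is selected and placements extend repertoires, since no private
slots remain.

**(iv) Implantation.** Positive labels are assigned uniformly at random;
pool sequences are drawn uniformly without replacement, each given a
carrier count from the signal model (denominator: positive repertoires by
default, configurable per the open question of how positive-cohort
calibration transfers to other class balances); placements go to distinct
positive repertoires, replacing private slots, and are recorded in the
ground-truth manifest. If a full pass leaves the instance budget unmet,
counts are topped up within each sequence's feasibility cap until the
required total is reached within ±5% (our tolerance choice) or caps are
exhausted — this is what makes "feasible" imply "achievable". Negative
repertoires receive nothing and are deliberately not screened for carrying
signal sequences by chance; a placement into a repertoire that already
carries the sequence by chance is redirected (repertoires are sets).

## Numerical choices

* **Binning.** Half-open `[left, right)` bins with clamping at both ends.
  Default p~gen~ bins split log10(p~gen~) at −12, −9, −6 (field practice
  shows about three informative decades-groups; the published figures use
  three bins without printing edges, so the edges are configuration, not
  code). Default incidence edges 0, 0.02, 0.05, 0.1, 0.2, 0.3, 1 — most
  non-signal public sequences sit below 2% incidence.
* **Within-bin sampling** is uniform — the maximum-entropy choice given
  that only bin-level probabilities are calibrated.
* **Fraction → count conversion** uses `floor(fraction * denominator)`,
  clamped to ≥ 2 (a public sequence is shared by definition). We first
  implemented round-half-up and found it systematically pushes fractions
  drawn just below a bin edge across the edge, so recalibrating a simulated
  cohort does not recover the generating model; the floor keeps every
  drawn count's implied fraction inside its bin, making
  calibrate∘simulate a fixed point up to sampling noise.
* **Empty rows** borrow the nearest trained row, preferring lower p~gen~
  (lower sharing — the conservative direction), with a warning.
* **Ties at the score threshold** are not called (strict `>`).
* **Reproducibility.** One top-level seed; `derive_seed(seed, label)` gives
  each stage (and each repertoire) its own substream, so identical seeds
  yield byte-identical output trees and partial reruns are stable.

## The toy engine, and what the tests do and do not show

All tests run against a built-in toy recombination model: junction =
V-prefix + i.i.d. middle + J-suffix. Because the decomposition is unique
given the gene calls, every receptor has exactly one generation path and
p~gen~ is an exact product — enumerable, with no recombination-event
summation. `toy_model_trb()` is parameterized to resemble TCRβ junctions
(middle lengths 4–10, natural-ish residue frequencies), spanning p~gen~
≈ 10⁻¹⁴–10⁻⁷ across several default bins while keeping baseline convergent
sharing low at depths of a few thousand — the regime in which real V(D)J
engines operate and the premise of the public-correction stage.

What the toy engine does *not* emulate: realistic V/J usage correlations,
positional residue biases, nucleotide-level generation with many
recombination paths per amino-acid sequence, clonal frequencies, or paired
chains. Passing tests therefore demonstrate the correctness of the
calibration, correction, implantation and audit machinery — not that
simulated repertoires are biologically indistinguishable from experimental
ones. The shipped incidence-model fixtures
(`synthetic_incidence_models()`, also under `inst/extdata/` with
`_synthetic` in the filenames) imitate the published shape of such models —
non-signal mass concentrated below 2% incidence, signal mass shifted
upward, nothing above 30% — but are invented; cohorts other than the one a
model was calibrated on require recalibration with
`calibrate_incidence()`, and smaller calibration cohorts inflate learned
incidence (the minimum public count 2 is a larger fraction of a smaller
cohort), which the tests verify directly.

## Problem sizes used in the test suite

The feasibility check is exact integer arithmetic at the worked example's
scale (200 repertoires). The binomial machinery is verified against
high-precision references for all counts at cohorts up to 50. The
calibrate∘simulate recovery runs at 500 repertoires × 2000 unique
sequences (per-row total-variation distance < 0.05 for rows with ≥ 500
training sequences); the shortcut-bias ordering at 50 × 5000 over ten
seeds — sizes at which the toy engine exercises every code path while the
whole suite stays comfortably within a coffee break on one CPU.

## A small end-to-end run

```{r example, fig.width = 6, fig.height = 4}
engine <- toy_model_trb()
models <- synthetic_incidence_models()
autoplot(models$public)

pool <- build_reference_pool(engine, 20000, seed = 5) |>
  filter(pgen > 1e-11, pgen < 1e-8) |>
  head(8)
config <- sim_config(n_repertoires = 30, positive_fraction = 0.5,
                     depth = 1000, public_fraction = 0.10,
                     witness_rate = 2, seed = 42)

dataset <- correct_public_component(config, engine, models$public) |>
  implant_signals(pool, config, models$signal)
glance(dataset)

audit <- audit_dataset(dataset)
truth <- distinct(dataset$manifest, junction_aa, v_call, j_call)
threshold_precision_recall(audit, truth, 35)
autoplot(audit, truth = truth, threshold = 35)
```

## Known limitations

Paired-chain repertoires, clonal frequency distributions, somatic
hypermutation and B-cell lineage structure are out of scope, as is any
dependence *between* public sequences within a repertoire (placements are
independent given the counts). The outlier score is a descriptive measure,
not a calibrated multiple-testing procedure. Signal-pool curation is the
user's responsibility: sequences with p~gen~ = 0 under the active engine
are flagged at feasibility time because the incidence models can never make
them public.
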