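---
title: "Desirability-based ensemble QSAR screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desirability-based ensemble QSAR screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`deqsar` implements a ligand-based virtual-screening protocol for settings in
which a compound must be active against *several* related biological systems
at once — the motivating case is a tumor studied through a panel of cell
lines, each with its own assay record. One classifier per cell line is never
the whole answer: a drug-repurposing candidate should look active to all of
them. The package therefore builds a pool of per-cell-line QSAR classifiers,
keeps the trustworthy ones, and aggregates their activity scores into a single
multi-objective desirability with which a screening library is ranked.

The pipeline has eight stages, each exposed as ordinary functions:

1. **Curation** (`parse_activity_table()`, `curate_compounds()`): assay
   records (IC50 / GI50 / EC50 standard values, micromolar) are mapped to a
   binary class — active below 10 uM, inactive above. A compound measured
   several times keeps the majority class only when its share strictly
   exceeds 75%, otherwise it is rejected. Structures are standardized
   (largest organic fragment, nitro normalization, canonical aromatic form)
   and duplicates are merged *before* classification, so replicate-level
   conflicts between duplicate structures resolve through the same majority
   rule. An id/SMILES blocklist withholds reference drugs for later
   screening.
2. **Descriptors** (`build_descriptor_table()`): 2D substructural fragment
   counts — atom/bond sequences of 2–8 atoms, atom-centered fragments,
   topological triplets.
3. **Feature reduction** (`frequency_filter()`, `mrmr_miq_select()`):
   fragments present in fewer than 1% of compounds are dropped; the rest are
   ranked by greedy mRMR with the mutual-information quotient and the top 500
   kept.
4. **Balancing** (`balance_dataset()`): the majority class is Ward-clustered
   (Euclidean distance) and downsampled to the minority size with per-cluster
   quotas, giving an exactly 1:1 dataset that still covers the chemical
   space.
5. **Split** (`split_train_external()`): a class-stratified 75/25
   train/external split; external compounds are never touched during feature
   selection or fitting.
6. **Base models** (`ga_select_features()`, `train_base_model()`): for each
   of six learner families (SVM with RBF kernel, random forest, neural
   network, decision tree, k-nearest neighbours, gradient-boosted trees) a
   genetic algorithm searches feature masks; the fitness of a mask is the
   mean balanced classification rate over stratified bootstrap resamples,
   scored out-of-bag. A model qualifies when its external accuracy is
   strictly above 0.8.
7. **Ensemble assembly** (`enumerate_model_combinations()`,
   `select_best_combination()`): with `m_k` qualified models in cell line
   `k`, all `prod(2^m_k - 1)` combinations (non-empty subsets per line, every
   line represented) are ranked on a labeled screening set; the winner
   maximizes BEDROC, with EF and AUC as tie-breaks.
8. **Screening and evaluation** (`screen_library()`,
   `early_recognition_report()`): the library is ordered by the global
   desirability `D1`, and judged by AUC, EF and BEDROC.

## The scores and metrics

**Per-model score.** Every learner is reduced to a probability-like activity
score in `[1e-6, 1]`: probability-capable learners report their active-class
probability; margin learners (the RBF-SVM) pass their decision value through
the logistic function, a monotone bounded map that needs no refit. The lower
clip keeps geometric means strictly positive; a compound with none of a
model's fragments is simply the all-zero descriptor vector and remains
scoreable.

**Desirability.** For cell line `k` with member scores `s_1..s_m`, the
desirability is the geometric mean `d(y_k) = (s_1 ... s_m)^(1/m)`; the global
score is again a geometric mean over the `k` cell lines,

    D1 = (d(y_1) d(y_2) ... d(y_k))^(1/k).

The geometric mean is deliberately conservative: a compound scored near zero
by any cell line cannot be rescued by the others, which is exactly the
multi-target semantics wanted in repurposing. `D1` is monotone in every
member score and bounded by the smallest and largest of them. Ties in `D1`
are broken by compound id, so rankings are invariant to input order.

**Classification metrics.** Models are summarized by accuracy, sensitivity,
specificity and the balanced classification rate

    BCR = ((SN + SP) / 2) * (1 - |SN - SP|),

which multiplies the usual balanced accuracy by a penalty for
sensitivity/specificity imbalance: a degenerate all-active predictor on a
balanced set has SN = 1, SP = 0 and BCR = 0, not 0.5. BCR is the GA fitness;
plain accuracy on the untouched external split is the qualification gate
(strictly above 0.8 — a model at exactly 0.8 does not qualify).

**Early recognition.** For a ranked list of `N` compounds containing `n`
actives at relative ranks `x_i`:

* `AUC = 1 - mean(x_i)` — the area under the accumulation curve;
* `EF(chi) = (a/n) / (k/N)` with `k = ceiling(chi * N)` top positions and `a`
  actives among them;
* `BEDROC(alpha) = (RIE - RIE_min) / (RIE_max - RIE_min)`, where
  `RIE` is the exponentially weighted hit sum
  `mean(exp(-alpha x_i))` normalized by its uniform expectation.

The weight `alpha` is calibrated by solving
`theta (1 - e^-alpha) - 1 + e^(-alpha z) = 0` for its positive root
(`solve_alpha()`): `z` is the list fraction where early recognition matters
and `theta` the share of the total weight that fraction should carry.
`theta = 0.80`, `z = 0.01` is the package default — the conventional
calibration, giving `alpha` of about 161; the equation always has the trivial
root 0, so the solver brackets away from it and polishes the positive root to
a residual below 1e-10.

### Numerical choices in the metrics

* **Ceiling cutoff.** The top-`chi` slice is `k = ceiling(chi * N)` entries.
  With `N = 772` and `chi = 0.01` that is 8 positions; with 2218 compounds it
  is 22 — the floor convention would give different worked values for both.
* **BEDROC extrema.** `RIE_min` and `RIE_max` are computed as the RIE of the
  explicit worst and best orderings (finite geometric sums), not the
  large-`N` continuous approximations `(1 - e^{±alpha Ra}) / (Ra (1 - e^{±alpha}))`
  sometimes quoted. The approximations can push BEDROC marginally outside
  `[0, 1]` at small `N`; the discrete extrema make BEDROC exactly 1 for a
  perfect ordering and exactly 0 for the inverted one, which the test suite
  asserts across random list shapes.
* **Strict ordering.** The metrics assume a strict ranking; score ties are
  resolved upstream by the id tie-break, never inside the metric.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| activity threshold | 10 uM | class boundary; a value of exactly 10 uM is unclassifiable and drops out of the majority vote (the class definitions are strict inequalities, and inventing a side would bias the vote) |
| majority share | > 0.75 | strict; 3-of-4 agreement (0.75) rejects |
| fragment lengths | 2–8 atoms | sequence and atom-centered path bounds |
| frequency filter | 1% | minimum presence fraction of a fragment column |
| mRMR k | 500 | descriptors kept per cell line |
| balancing clusters | explicit `n_clusters` (or height `h`) | replaces a by-eye dendrogram cut; no automatic elbow detection, so runs are reproducible |
| train fraction | 0.75 | class-stratified, largest-remainder rounding |
| GA (full scale) | 50 x 30 x 100 | population, generations, bootstrap resamples |
| GA (desk scale) | 20 x 10 x 25 | `study_settings()` default, see below |
| GA operators | tournament 3, uniform crossover 0.8, mutation 1/L, elitism 1, init bit prob 0.1 | unspecified in the protocol; fixed, all in `ga_config()` |
| qualification | external AC > 0.8 | strict inequality |
| decoys | 50 per active | property-matched from the pool |
| theta, z, chi | 0.80, 0.01, 0.01 | early-recognition calibration |

## Design decisions where the design was open

* **Fragment label syntax.** The four fragment families are reproduced at the
  level of *counting semantics*, with the package's own canonical labels
  (element plus `a` for aromatic atoms; `-`, `=`, `#`, `~` bonds; paths read
  in whichever direction is lexicographically smaller). Binary compatibility
  with legacy fragmentation tools is a non-goal. The "atom-centered" and
  "fixed-length atom-centered" variants differ only in whether rooted paths
  of all lengths up to the maximum, or of exactly one length, contribute;
  both are available behind `fragment_config()`, the fixed variant off by
  default.
* **MI discretization.** Fragment counts are binarized to presence/absence
  before mutual information: counts are sparse and heavy-tailed and no
  discretization was prescribed. MI is measured in nats; the unit cancels in
  the MIQ quotient. Near-zero mean redundancy (below 1e-12) is handled by a
  capped quotient with relevance and label as deterministic tie-breaks; MIQ
  scores are compared at 12 significant digits so mathematically tied
  features (equal up to floating-point summation order) resolve through the
  tie-breaks rather than through rounding noise.
* **Bootstrap fitness.** "Random splits (bootstrap sampling)" is read as
  stratified bootstrap resampling with out-of-bag scoring: train on a
  with-replacement resample of each class, score BCR on the never-drawn
  compounds. This keeps every fitness evaluation a genuine hold-out estimate
  and is reproducible; all masks are scored against the same resample
  sequence (common random numbers), which together with the memoised fitness
  cache makes elitism traces exactly nondecreasing.
* **Tautomers.** Structure standardization covers salt stripping, nitro
  normalization and aromatic perception; full tautomer canonicalization
  rules are not well defined and are deliberately out of scope.
* **Ward clustering.** `hclust(method = "ward.D2")` on unscaled Euclidean
  distances — the textbook Ward criterion. The "interval measure" of the
  original SPSS workflow is read as plain Euclidean distance on the raw
  descriptor vectors.
* **Combinations.** Every cell line must be represented in a combination
  (`k` in `D1` is the cell-line count); dropping a line entirely would make
  `D1` values incomparable across combinations.

## The synthetic study

`synthetic_study()` generates everything the pipeline consumes, with no
external data: per-cell-line activity tables, a screening set, and ground
truth. Molecules are assembled from a template grammar (aromatic and
saturated rings, short chains, 26 common substituents), which guarantees
valence-valid, parseable structures. Each pseudo-cell-line plants a
pharmacophore — a substituent such as a nitro group, a carboxylic acid or a
trifluoromethyl — on about 45% of its library; molecules containing the
pharmacophore draw assay values log-uniformly below 10 uM, the rest above,
and labels flip at the noise rate (default 0.05). A small panel of
multi-target reference actives carries *every* line's pharmacophore and is
withheld from modeling via the blocklist; the screening set is these
references plus property-matched decoys (nearest pool molecules in
heavy-atom count / ring count / heteroatom fraction, drawn from a
pharmacophore-free pool at 50 per active) plus the inactives removed during
balancing — mirroring the actives + decoys + balance-leftovers construction
of a realistic validation set.

What the generator does *not* emulate: real assay-value distributions and
inter-assay noise structure, scaffold diversity of medicinal chemistry
series, activity cliffs, and decoys matched on full physicochemical profiles
(the matching uses cheap graph-derived properties). Passing the end-to-end
test therefore shows that the machinery — curation, descriptors, selection,
GA, desirability assembly, metrics — recovers a genuine planted signal under
noise; it does not certify performance on real screening data.

## Problem sizes and determinism

The package's desk-scale defaults (`study_settings()`) run the full protocol
— 3 pseudo-cell-lines of 300 compounds, three learner families per line, GA
with population 20, 10 generations and 25 bootstrap resamples — in minutes on
one CPU; the full-scale GA settings (50 x 30 x 100, all six learners) are the
`ga_config()` defaults and scale linearly. All randomness flows from explicit
seeds through `withr::with_seed()`; regenerating a study, a split, a GA run
or a whole pipeline with the same seed is byte-identical, and the pipeline
manifest records MD5 digests of every stage output so cached results are
verified before reuse.

## Known limitations

* The GA fitness landscape is evaluated over the mRMR-ranked candidate set;
  features discarded by mRMR cannot be recovered downstream.
* k-nearest-neighbour scores are vote fractions, so their desirabilities are
  coarsely quantized; in small ensembles this can produce ties that the id
  tie-break resolves arbitrarily (but reproducibly).
* The chemistry backend delegates SMILES parsing and aromaticity perception
  to OpenBabel; structures OpenBabel cannot parse are rejected at curation
  rather than repaired.
* Early-recognition metrics require a strict ranking and at least one active
  and one inactive; degenerate screening sets are refused with explicit
  errors rather than given imputed values.
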