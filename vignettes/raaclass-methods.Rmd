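---
title: "Reduced-alphabet composition classification: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-alphabet composition classification: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raaclass)
```

## The model

Protein families often differ in bulk sequence composition long before
they differ in alignable motifs. `raaclass` exploits this for family
assignment — the motivating case being the four structural types of
J-proteins/Hsp40 co-chaperones, whose domain architectures (J-domain, G/F
linker, zinc finger) leave a measurable compositional footprint — by a
three-stage model:

**Alphabet reduction.** A *cluster profile* is an ordered partition of the
20 canonical residues into `k` clusters; the built-ins (CP13, CP11, CP9,
CP8, CP5, plus the identity CP20) come from a clustering of residues by
their protein-blocks structural preferences and form a nested chain of
refinements. Reduction maps each residue to its 0-based cluster index.
Working over a reduced alphabet shrinks the tripeptide space from
`20³ = 8000` to, e.g., `8³ = 512` (CP8), which matters because the
feature-to-sample ratio, not the classifier, is usually the binding
constraint on family datasets with a few dozen members per class.

**n-peptide composition.** For word length `n ∈ {1,2,3}` a sequence of
length `L` contributes `L − n + 1` sliding windows; the feature vector is
the empirical distribution `f_i = N_i / W` over the `D = k^n` reduced
words, where `W` is the number of valid windows. Features are ordered
lexicographically over cluster indices, leftmost window position most
significant — the ordering is arbitrary in principle but fixed and
documented because a fitted SVM is only portable if the coordinate order
is reproducible.

**Classification.** An RBF-kernel SVM, one binary machine per class pair
(`k(k−1)/2`, libsvm's one-vs-one voting). Composition vectors are already
on a common `[0, 1]` scale, so no feature standardization is applied
(standardizing frequency features would also blow up rare-word noise).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `profile` | CP8 | cluster profile; CP8×`n`=3 gives 512 features, the usual sweet spot |
| `n` | 3 | word length (1–3); capped at 3 so the dimension table stays honest |
| `C` | 1 | SVM regularization (unitless); search `2⁻⁵…2¹⁵` |
| `gamma` | `1/D` | RBF width (inverse squared feature distance); search `2⁻¹⁵…2⁻⁵` |
| `folds` | 5 | stratified CV folds inside `grid_search()` |
| `alpha` | 0.05 | level for both the ANOVA screen and the LSD pairwise tests |
| `confidence_threshold` | 0.999 | minimum `1 − p` for a reported enriched word |

The grid bounds follow standard libsvm practice in powers of two with
exponent step 1 (21 × 11 = 231 candidate pairs); ties are broken toward
smaller `C` then smaller `gamma`, i.e. toward the least complex model
among equals.

## Cross-validation protocol

`jackknife()` re-trains on all-but-one sequence `N` times and scores the
`N` held-out predictions jointly — the least arbitrary protocol for small
family classes, and deterministic. Hyperparameters are chosen **once** by
`grid_search()` on the full dataset and then held fixed across folds.
This matches the classical protocol for this model family but carries a
mild optimistic bias (the held-out sequence participated in model
selection). Users who need unbiased estimates can nest the search
manually: `grid_search()` on each fold's training subset is the same code
path. We chose not to hard-wire a nested mode because at `N` ≈ 10³ and
231 grid points it multiplies cost by ~5 × 231 while changing reported
accuracy by far less than the class-imbalance effects that dominate these
datasets.

`kfold()` stratifies folds by class with a seeded shuffle. `k = N` is
exactly the jackknife and is routed there; otherwise `k` may not exceed
the smallest class size, so every training fold retains every class.

### Metrics

Per class, one-vs-rest: `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, the binary
Matthews correlation coefficient, and `OA = Σ TP(i)/N`. A zero
denominator makes the metric **undefined, reported as `NA`** — a rare
class that is never predicted has an undefined MCC, and printing 0 there
would misstate "no better than chance" as a measured value.
`write_report(compat = TRUE)` restores the print-0 convention for
compatibility with published table layouts.

## Composition statistics

`anova_lsd()` runs, per residue, a one-way ANOVA on **per-sequence**
frequencies (sequence-level variance is the right error term; pooling
counts would treat residues within one sequence as independent), then
Fisher's LSD on all class pairs where the ANOVA rejects: pairwise t
statistics on the pooled within-group mean square with `N − k` degrees of
freedom. LSD is deliberately uncorrected — the ANOVA gate is its only
multiplicity control — and the output says which class of each pair is
enriched. Residues with zero variance everywhere are flagged undefined
(`NA`) rather than tested.

`binomial_enrichment()` tests each reduced word `t` in each class `c`:
`p = P(X ≥ m)` with `X ~ Binomial(M_c, q_t)`, `m` the word's window count
in the class, `M_c` the class's total windows. The background `q_t` is
the **pooled whole-dataset frequency** of `t` (the natural null for
"over-represented in this family relative to the collection"); a uniform
`1/D` background is selectable (`background = "uniform"`). Because class
`c`'s own windows are part of the pooled estimate, the test is mildly
conservative — more so with few classes. No multiple-testing correction
is applied; the default confidence threshold 0.999 corresponds to
`p < 10⁻³` per word, and users scanning thousands of words should expect
about one background hit per thousand tests.

## Degenerate inputs and numeric choices

* **Non-canonical residues** (X, B, Z, U, O, gaps): the default `mask`
  policy removes the symbol and records a *window break*, so no n-peptide
  window spans the masked position and the denominator `W` counts only
  surviving windows — frequencies remain a probability distribution.
  A `strict` policy errors with residue and position. We do not invent a
  cluster assignment for ambiguity codes.
* Sequences empty after masking, or with no window of length `n`, raise
  errors naming the sequence; `encode_dataset(on_error = "skip")` drops
  and logs them instead.
* MCC products are computed in double precision as
  `sqrt(a·b)·sqrt(c·d)` to avoid integer overflow on large tallies.
* The binomial tail uses `pbinom(m − 1, M, q, lower.tail = FALSE)`
  (exact; verified against the brute-force point-mass sum to 1e−12 for
  `M ≤ 20`).
* The Gaussian Naive Bayes baseline floors class-conditional standard
  deviations at 1e−6; sparse composition features are often constant
  within a class, and a zero sd makes the likelihood degenerate.

## The synthetic-data generator

`generate_dataset()` draws residues i.i.d. from a per-class distribution
(uniform background 0.05 per residue by default, plus additive per-class
shifts, renormalized; shifts that drive any probability negative are
rejected before generation), with lengths uniform on a stated range and
optional planted words written over windows left-to-right at a stated
per-window probability (length-preserving). Defaults used across the test
suite — class sizes of tens to a few hundred, lengths 100–300, biases of
0.03–0.10 — are in the range of real family datasets and of effect sizes
that composition methods are expected to resolve.

What it deliberately does **not** emulate: Markov/neighbor structure,
domain architecture, phylogenetic correlation between sequences, and
shared homology. Passing tests therefore demonstrate that the pipeline
recovers *composition* signal correctly — not that any particular real
family is predictable, and not that performance on homology-redundant
data is unbiased. Real datasets should be redundancy-reduced externally
(e.g. CD-HIT at ≤40% pairwise identity) before evaluation; the package
records, but cannot verify, a declared identity threshold in dataset
metadata.

### Problem sizes used in the validation suite

Chosen to make each property measurable with headroom: counting-oracle
equivalence on 200 random sequences (length ≤ 50) across all profiles and
`n`; metric arithmetic on 100 random tallies against a
correlation-of-indicators oracle; jackknife on 40-sequence 4-class sets
(exact on disjoint-alphabet classes; at the majority-rate binomial band
under label permutation); enrichment null calibration on 8 × 125 = 1,000
word hypotheses; ANOVA null calibration over 500 replicates of 4 × 12
sequences (10,000 residue tests, rate checked against the 95% binomial
band around `alpha`).

## Known limitations

* Composition features ignore residue order beyond the n-window; families
  distinguished mainly by domain arrangement at equal composition are out
  of reach.
* Grid search optimizes overall accuracy, which on imbalanced data is
  dominated by the majority class; rare-class sensitivity can be poor
  even at high OA (visible in the README example), and the optional
  `class_weights` hook is the first remedy.
* The jackknife protocol's single global hyperparameter selection is
  mildly optimistic (above).
* Profiles are taken as given; deriving new cluster profiles from
  structural data is out of scope, though any user partition is accepted
  via `cluster_profile()` or the plain-text profile file format.
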