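---
title: "Methods: imbalance-aware QSAR modelling of AUR-TPO inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware QSAR modelling of AUR-TPO inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aurqsar)
```

## The modelling problem

Thyroperoxidase (TPO) catalyses key steps of thyroid-hormone synthesis;
chemicals inhibiting it are candidate thyroid disruptors. The Amplex
UltraRed (AUR-TPO) assay measures TPO inhibition fluorometrically, but a
positive signal can be confounded: a compound may dim the readout by
inhibiting enzymes non-specifically (flagged by a luciferase assay) or
by killing the cells (flagged by a cytotoxicity assay). A usable QSAR
endpoint therefore needs (i) structure-level curation, (ii) a
selectivity filter separating genuine TPO inhibitors from confounded
hits, and (iii) classifiers that survive a heavily imbalanced class
distribution (~83% inactives). This vignette documents how each stage
is defined here, which parameters matter, and which choices were open
and how they were settled.

## Structure curation

Curation uses OpenBabel (through ChemmineOB) for parsing,
canonicalization, charge neutralization and InChI generation. The rules,
applied in order by `standardize_structure()`:

1. **Parse failure** → `rejected_no_unique_structure`.
2. **No carbon anywhere** → `rejected_inorganic`.
3. **Multi-fragment structures**: a structure is a *salt* only when
   exactly one fragment contains carbon; the carbon-free counter-ions
   are stripped. Two or more organic fragments are a *mixture* and
   rejected. This is the narrowest reading that keeps common salts
   (sodium benzoate) while discarding genuine mixtures.
4. **Elements**: the modelled chemical space is restricted to H, C, N,
   O, F, Br, I, Cl, P, S. A metal or metalloid in the organic fragment
   marks the compound organometallic (`rejected_inorganic`); any other
   off-list element (Se, Si, B, ...) gives `rejected_element`. We define
   "organometallic" at the fragment level — a metal in the same
   connected component as carbon — rather than by explicit carbon–metal
   bond perception; for a single covalently connected fragment the two
   notions coincide for practical purposes, and the fragment rule is
   exactly reproducible across toolkits.
5. **Neutralization and canonicalization**: charges with a neutral form
   are neutralized (carboxylates, protonated amines); permanent cations
   (quaternary nitrogen) are left as they are and the structure is still
   accepted.

**Duplicates.** Records are grouped by standard InChI rather than by
canonical SMILES. The InChI mobile-hydrogen layer maps heteroatom
tautomers (2-hydroxypyridine / 2-pyridone) to one identifier, which is
the reproducible way to make deduplication "tautomer-aware" without
committing to one toolkit's tautomer canonicalizer; keto–enol pairs
remain distinct, which matches chemical intuition for stable species.
Groups with concordant categories collapse to a single record; groups
whose categories contradict each other are removed entirely. By default
contradiction is judged on the *binary* hit-call (inactive versus any
active stratum); the stricter `conflict_on = "category"` variant treats
any INA/NSE/LSE/HSE disagreement as contradictory, because two records
disagreeing on, say, HSE versus LSE produce different labels under some
partitioning schemes. Both rules are deterministic; the binary rule is
the default because a selectivity-stratum disagreement between
replicates usually reflects assay noise around a threshold rather than a
genuine activity conflict.

## Selectivity and partitioning

For a positive hit-call the selectivity is

```
SEL = min(logIC20_luc, logIC20_cyto) − logIC20_tpo
```

The orientation is fixed by what the categories must mean: a compound
whose TPO IC20 is far *below* the confounder IC20s is a selective
inhibitor, and only `confounder − TPO` makes large positive SEL mean
high selectivity. The two confounders are combined by the minimum — the
most conservative choice, treating a compound as confounded if *either*
assay fires at comparable potency. A missing confounder IC20 defaults
to `+Inf` ("no confounding detected"); the ceiling is configurable
because upstream data sources differ in how censored assays are coded.

Categories: NSE (SEL < 0), LSE (0 ≤ SEL < 1), HSE (SEL ≥ 1); absent SEL
is INA. Both boundary values land in the upper category (SEL = 0 → LSE,
SEL = 1 → HSE).

Four partitioning schemes map categories to the binary endpoint
(`hse-only`, `hse-lse`, `all-active`, `hse-vs-ina`); INA is always
inactive, and `hse-vs-ina` discards LSE/NSE entirely, keeping only the
most reliable hit-calls. With category counts (751, 105, 64, 153) the
schemes yield 1073/1073/1073/904 usable compounds.

**Splits.** The test set receives `ceiling(f·N)` compounds; per-class
counts follow the largest-remainder rule on the exact quotas. This is
the only deterministic allocation consistent with an 80/20 split of
751 + 153 giving a 181-compound test set of 150 inactives and 31
actives. Assignment within a class is a seeded uniform draw, so splits
are bit-reproducible.

## Descriptor preprocessing

`prune_descriptors()` removes, in order: columns with missing values;
near-constant columns (population SD < 0.01 — the divisor convention is
irrelevant at this threshold but must be fixed, and N is used); and one
member of every pair with |Pearson r| strictly above 0.95. The
correlation filter scans columns left to right and always keeps the
earlier column of a correlated pair — the retained *set* depends on this
tie-break, so it is documented and tested against a brute-force oracle.
Scaling statistics (mean, population SD) are fitted on training rows
only and applied unchanged to test and external compounds; pruning is
likewise fitted on the training set.

## Feature ranking and the subset sweep

Two rankings are provided. *Gini importance* is the mean decrease in
Gini impurity across the trees of a forest (balanced bootstraps when the
downstream model is a balanced forest), normalized to sum to one.
*Permutation importance* is the drop in balanced accuracy when one
column is shuffled `n_repeats` times (default 10 — standard practice,
configurable). The scoring forest is fitted on 75% of the training rows
and scored on the held-out 25%: in-sample permutation importance of a
deep forest is near zero for every feature because the forest can
interpolate the training set, so held-out scoring is the only version
that discriminates. Ties in either ranking break by stored column
order.

`sweep_subsets()` evaluates the candidate sizes 20, 30, 50, 100, 120,
130, 150, 160, 170, 200, 250, 300 (clipped to the available feature
count) by k-fold cross-validated balanced accuracy. Folds are *shared*
across sizes for a given seed — paired comparisons have lower variance
than refolding per size — and ties go to the smallest size, preferring
parsimony.

## Rebalancing

Training sets are rebalanced; test and external sets never are — their
natural imbalance is exactly what an honest evaluation must face, and
the pipeline enforces this by construction.

*SMOTE* interpolates synthetic minority points,
`x_new = x_i + u·(x_nn − x_i)` with `u ~ U(0,1)` and `x_nn` one of the
k = 5 nearest minority neighbours (the classical default; neighbour
search among minority samples only, Euclidean metric in the scaled
space). The RNG contract — three draws per synthetic point in a fixed
order from a named substream — is documented so an independent
implementation can replay the stream point-for-point, which the test
suite does.

*Balanced random forests* draw, for every tree, a bootstrap of
`n_min` samples from each class (`balanced_bootstrap_indices()`), i.e.
per-tree undersampling of the majority class. BRF therefore refuses an
external resampling plan: combining both would distort the class prior
twice.

## Models and tuning

Four families: balanced random forest, random forest, k-nearest
neighbours, RBF SVM. Default grids are small and standard — knn
k ∈ {1,3,5,7,9,11} × {uniform, inverse-distance}; forests
trees ∈ {100,250,500} × mtry ∈ {√p, log₂p}; SVM C ∈ {0.1,1,10,100} ×
γ ∈ {scale, 0.01, 0.001} — and fully overridable. Tuning is exhaustive
grid search scored by mean balanced accuracy over stratified 10-fold
cross-validation, ties resolved to the first grid point in declaration
order. Rebalancing happens *inside* each training fold only: SMOTE
before splitting would place synthetic near-copies of validation
compounds into the training folds and inflate the CV score.

Probabilities: forests report the fraction of trees voting active; knn
the (optionally distance-weighted) fraction of active neighbours; SVM a
sigmoid-calibrated score from its internal five-fold calibration. A
compound is called active when its active-class probability *exceeds*
0.5; exactly 0.5 yields inactive — the conservative direction for a
screening endpoint where a false "active" triggers follow-up testing.

## Validation

Cooper's statistics (SEN, SPE, BA) and the Matthews correlation
coefficient are computed exactly from the confusion matrix; a zero
factor in the MCC denominator gives MCC = 0 (the standard convention).
Reported values are rounded half-up to two decimals; the API keeps full
precision.

*Y-scrambling* permutes the labels uniformly (class counts are preserved
automatically), retrains, and scores each permutation by cross-validated
BA; `p = (c+1)/(n+1)` with `c` the number of permutations beating the
unpermuted baseline, so p is never zero and its floor at n = 100 is
1/101 ≈ 0.01.

*Applicability domain*: predictions are filtered by predicted-class
probability thresholds (default grid 0.5–1.0 in steps of 0.05); each
threshold yields a coverage and a BA on the retained subset. Coverage at
0.5 is exactly 1 by the probability convention; when a threshold empties
one class the BA is reported as undefined and flagged rather than
extrapolated.

*Consensus*: unanimity between two models — a label is issued only when
both agree, conflicts are counted but unlabelled, and metrics on the
concordant subset always balance (matrix total = coverage × n).

## The synthetic generator

`synth_feature_table()` draws class-conditional Gaussians: 751 inactive
and 153 active compounds (the 83% imbalance of the most reliable
partitioning condition), 50 descriptors, 5 informative with a one-SD
mean shift for actives. The Gaussian model was chosen *because* it has a
closed form: the Bayes-optimal balanced accuracy for a d-dimensional
unit-variance shift of size δ per coordinate is `Φ(√d·δ/2)` — ≈ 0.87 at
the defaults — which gives analytic upper bounds for accuracy tests and
a known ground truth for feature-recovery tests. What it deliberately
does **not** emulate: the covariance structure, discreteness and heavy
tails of real molecular descriptor blocks, activity cliffs, or any
relation between the SMILES fixtures and the feature table. Passing
tests on this generator therefore demonstrate that the machinery is
correct and honestly evaluated, not that any particular accuracy will
transfer to real descriptor data.

The assay-table generator emits log IC20 triples whose `category` column
is exactly `classify_selectivity()` applied to the generated values, and
the SMILES fixture list triggers every curation status at least once.

## Problem sizes used in the validation suite

The test suite exercises the full study shape (904 × 50) where the
result depends on it — scrambling nulls, feature recovery, the
end-to-end pipeline — and smaller shapes (≈ 180 × 10–15) for
per-operation properties and the behavioural tendency checks (BRF versus
RF balance, SMOTE's effect on sensitivity), with forests of 50–250 trees
and 3–10 folds. These sizes are large enough that the asserted
tendencies are stable across the seeds tested while keeping the whole
suite quick to run; the scrambling protocol uses the 50-tree reduced
forest documented in `y_scramble()`, whose null distribution is
insensitive to forest size.

## Known limitations

* Descriptor computation is out of scope; results depend on whatever
  backend produced the input matrix, and the published descriptor
  counts (619 retained descriptors) are not reproducible without the
  original proprietary software.
* OpenBabel's neutralization handles common charge patterns; exotic
  zwitterions may survive with formal charges (they are still accepted
  and canonicalized consistently).
* The element-based organometallic rule cannot distinguish a true
  carbon–metal bond from a metal coordinated in the same fragment; both
  are rejected, which errs on the side of exclusion.
* SVM probability calibration is best-effort (five-fold sigmoid inside
  e1071); the applicability-domain analysis is designed around the two
  finalist model families (BRF, KNN), whose probabilities are vote and
  neighbour fractions.
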