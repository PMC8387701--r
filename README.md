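# aurqsar

Imbalance-aware QSAR classification of thyroperoxidase (TPO) inhibition
from Amplex UltraRed (AUR-TPO) assay data.

Thyroperoxidase catalyses the synthesis of thyroid hormones; chemicals
that inhibit it are candidate thyroid disruptors, and high-throughput
AUR-TPO screens produce the data needed to train *in silico* filters for
the thousands of environmental chemicals that will never be assayed
individually. Two features of those screens shape everything in this
package: positive hit-calls must be cleaned of confounded signals
(non-specific enzyme inhibition, cytotoxicity), and the data are heavily
imbalanced towards inactives (~83%). `aurqsar` implements the complete
workflow for building and rigorously validating binary QSAR classifiers
under those conditions. It is aimed at computational toxicologists and
cheminformaticians working with screening-derived endpoints.

## What it does

* **Structure curation** — SMILES standardization through OpenBabel
  (ChemmineOB): salt stripping and charge neutralization, rejection of
  inorganics, organometallics, mixtures and structures with elements
  outside {H, C, N, O, F, Br, I, Cl, P, S}, and tautomer-aware
  deduplication via InChI hashing, with contradictory duplicate groups
  removed.
* **Hit-call stratification** — the selectivity of an active hit is
  `SEL = min(logIC20_luc, logIC20_cyto) − logIC20_tpo`; actives are
  stratified as NSE (SEL < 0), LSE (0 ≤ SEL < 1) or HSE (SEL ≥ 1), and
  four partitioning schemes map the INA/NSE/LSE/HSE categories onto a
  binary endpoint. Train/test splits are stratified with
  largest-remainder allocation.
* **Descriptor preprocessing** — removal of descriptors with missing
  values, near-constant descriptors (SD < 0.01) and one member of every
  pair with |r| > 0.95; z-scaling with training-set statistics only.
* **Feature selection** — Gini-importance and permutation-importance
  (balanced-accuracy drop) rankings, plus a cross-validated sweep over
  subset sizes 20–300.
* **Imbalance handling** — SMOTE oversampling of the minority class
  (`x_new = x_i + u·(x_nn − x_i)`), or balanced random forests whose
  every tree trains on an undersampled balanced bootstrap.
* **Models** — balanced random forest, random forest, k-nearest
  neighbours and RBF SVM, tuned by exhaustive grid search scored with
  balanced accuracy in stratified 10-fold cross-validation (rebalancing
  applied inside training folds only).
* **Validation** — Cooper's statistics (SEN = TP/(TP+FN),
  SPE = TN/(TN+FP), BA = (SEN+SPE)/2), Matthews correlation
  (MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))), Y-scrambling
  with p = (c+1)/(n+1), probability-threshold applicability-domain
  curves, and two-model unanimity consensus.
* **Synthetic fixtures** — a seedable generator emulating the study
  shape (751 inactive / 153 active, class-conditional Gaussian
  descriptors with known informative columns), so the whole pipeline is
  testable without any proprietary descriptor software.

Descriptor computation itself is out of scope: the package consumes any
numeric descriptor matrix (id × descriptor CSV), whatever backend
produced it.

## Worked example

```r
library(aurqsar)

# synthetic study-shaped data: 751 inactive / 153 active, 50 descriptors,
# 5 of them informative at a one-SD class shift
ft  <- synth_feature_table(synth_config(seed = 42))
spl <- stratified_split(ft$y, test_fraction = 0.2, seed = 42)
tr  <- spl$split == "TrS"

zs <- zscore_fit(ft$x[tr, ])        # scaling fitted on the training set only
xs <- zscore_apply(ft$x, zs)

rk <- rank_features(xs[tr, ], ft$y[tr], method = "gini", seed = 42)
head(rk, 5)
#>   rank name      score method
#> 1    1 D003 0.09989015   gini
#> 2    2 D005 0.09929154   gini
#> 3    3 D001 0.09531303   gini
#> 4    4 D002 0.08203681   gini
#> 5    5 D004 0.07147664   gini

model <- qsar_train(xs[tr, ], ft$y[tr], algorithm = "brf",
                    grid = data.frame(ntree = 250, mtry_rule = "sqrt"),
                    nfolds = 10, seed = 42)
model
#> QSAR classifier: BRF (50 features, per-tree balanced-bootstrap rebalancing)
#>   tuned parameters: ntree = 250, mtry_rule = sqrt
#>   10-fold CV balanced accuracy: 0.853

pred <- qsar_predict_table(model, xs[!tr, ])
rep  <- classification_report(ft$y[!tr], pred$label)
#> test set: SEN 0.58  SPE 0.95  BA 0.76  MCC 0.57 (n = 181)

domain_curve(pred$probability_predicted_class, ft$y[!tr], pred$label,
             thresholds = c(0.5, 0.65, 0.8))
#>   threshold  coverage n_kept        ba degenerate
#> 1      0.50 1.0000000    181 0.7636559      FALSE
#> 2      0.65 0.6574586    119 0.9000000      FALSE
#> 3      0.80 0.2486188     45        NA       TRUE
```

The ranking recovers the five informative descriptors (D001–D005) at the
top. The balanced forest reaches a test-set balanced accuracy of 0.76 on
the held-out 181 compounds (150 inactive, 31 active), and restricting to
predictions with predicted-class probability ≥ 0.65 raises BA to 0.90 at
66% coverage — the coverage/accuracy trade that defines the model's
applicability domain. At 0.80 the retained subset loses one class
entirely and BA is flagged as undefined.

The same workflow is scriptable end to end (`run_pipeline()`, or the
`exec/aurqsar` command line: `synth`, `curate`, `label`, `run`, `train`,
`predict`, `evaluate`).

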