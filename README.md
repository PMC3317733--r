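# lumipred

Classification of bioluminescent proteins — luciferases, photoproteins and
relatives — from the evolutionary information in their PSI-BLAST profiles.

Bioluminescent proteins from different taxa share little raw sequence
identity, so `lumipred` works from the position-specific scoring matrix
(PSSM): the L × 20 table of per-position log-odds scores that PSI-BLAST
computes against a large protein database. The package parses the ASCII
PSSM dialect, condenses a variable-length profile into a fixed-length
descriptor, and classifies with an RBF-kernel support vector machine.

Two descriptors are implemented:

* **PSSM-AC** — the auto-covariance of each profile column *j* at lags
  *d* = 1…*lg*,

  AC(d, j) = (1/(n−d)) Σᵢ (Pᵢⱼ − P̄ⱼ)(P₍ᵢ₊d₎ⱼ − P̄ⱼ),

  giving *lg* × 20 features (600 at the reference *lg* = 30). It captures
  *local sequence-order information*: how conservation at one position
  co-varies with conservation d residues downstream.
* **PSSM-400** — the order-free composition descriptor: per residue type,
  the mean PSSM row over that residue's positions (20 × 20 = 400
  features).

The SVM decision function f(x) = Σᵢ yᵢαᵢ exp(−γ‖xᵢ−x‖²) + b is fitted with
cost C and kernel width γ selected by grid search (the standard LIBSVM
grids C ∈ 2⁻⁵…2¹⁵, γ ∈ 2⁻¹⁵…2³) under stratified 10-fold
cross-validation; sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/total and the ROC/AUC from pooled out-of-fold scores evaluate the
result. A maximum-lag sweep (`sweep_lag()`) reproduces the model-selection
step that chose *lg* = 30 on the real corpus. Because real profiles need a
local PSI-BLAST setup, a seeded synthetic generator emits corpora whose
class signal lives purely in per-column AR(1) lag correlation, making the
entire pipeline testable at desk scale.

## Worked example

```r
library(lumipred)

spec <- synth_spec(seed = 1)   # 100 AR(1) rho=0.7 positives vs 100 white-noise negatives
corpus <- generate_profiles(spec)
fit <- pssm_svm(corpus$profiles, corpus$labels, encoder = "pssm-ac",
                lg = 5, folds = 10, seed = 1)
fit
```

```
RBF-SVM bioluminescence classifier
  encoder:   pssm-ac|lg=5|normalization=raw
  training:  200 instances (100 +1 / 100 -1), 100 features
  selected:  C = 0.03125, gamma = 3.05176e-05 (grid of 110 pairs, 10-fold CV)
  CV accuracy (mean over folds): 1.0000
```

The fitted object carries the full grid-accuracy table (`fit$grid`) and
the out-of-fold cross-validation report:

```r
fit$cv
#> Evaluation report (200 instances)
#>   TP 100  TN 100  FP 0  FN 0
#>   Sn 1  Sp 1  ACC 1  AUC 1
#>   mean per-fold accuracy 1 over 10 folds

predict(fit, corpus$profiles[c(1, 2, 101, 102)])
#>        id        score label
#> 1 pos_001  0.013075775     1
#> 2 pos_002  0.006602204     1
#> 3 neg_001 -0.020630803    -1
#> 4 neg_002 -0.021442920    -1
```

The synthetic classes differ *only* in lag correlation — their marginal
score distributions match — so the order-sensitive PSSM-AC descriptor
separates them perfectly while the order-free PSSM-400 descriptor on the
same corpus stays near chance (CV accuracy 0.63 here), and on a null
corpus with `rho_pos = rho_neg` the whole pipeline returns chance-level
accuracy. That dissociation is the synthetic analogue of PSSM-AC
outperforming PSSM-400 on the real bioluminescence corpus.

Real data enter the same way: `parse_pssm()` one file per sequence (or
`run_psiblast()` to generate them), `read_fasta()` + `filter_by_length()`
for dataset construction, then `pssm_svm()` / `evaluate_cv()` /
`evaluate_independent()`. A thin command-line wrapper over the same
functions ships in `inst/cli/lumipred.R` (`simulate`, `encode`, `cv`,
`train`, `predict`, `sweep`).

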