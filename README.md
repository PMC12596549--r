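# ihdri

Fair and explainable recurrent risk models for ischemic heart disease
(IHD) prognosis from tabular clinical records in the UCI Heart Disease
schema.

`ihdri` is for biostatisticians and clinical-ML researchers who want a
small, fully reproducible pipeline that takes the classic 14-field
heart-disease record format end to end: missing-value imputation,
leakage-safe preprocessing, a recurrent classifier with fairness-aware
training, Shapley-value explanations, and a cross-validation / ablation /
fairness-report harness. Everything runs on synthetic cohorts generated by
the package itself, so no download is required to exercise or test any
part of it.

## The model

Each encoded record (25 columns after min–max scaling and one-hot
expansion) is read as a sequence of T = 25 scalar tokens. A bidirectional
LSTM produces per-step states `h_t = [h_f(t); h_b(t)]`. A parallel
residual feature track and a learned attention gate refine the
representation:

    XF(t+1) = f_a(W_i x(t) + W_r XF(t)) + λ (XF(t) − f_a(W_i x(t) + W_r XF(t)))
    M(t)    = σ(W_m H(t) + b_m)
    H(t+1)  = (1 + M(t)) ⊙ XF(t) + h(t)
    ŷ       = σ(W_o · H(T) + b_o)

with λ ∈ [0, 1] a fixed residual-influence coefficient (default 0.5).
Training minimizes the fairness-aware reweighted binary cross-entropy

    L = − Σ_i w_i [ y_i log ŷ_i + (1 − y_i) log(1 − ŷ_i) ],

where `w_i = 1 / p(g_i)` are inverse-frequency weights over demographic
groups (sex × age-bin at 50 years), rescaled to mean 1. Transfer learning
initializes the recurrent and attention parameters from a checkpoint
pretrained on a larger synthetic source-domain corpus; the output head is
always fine-tuned fresh. Backpropagation through time, Adam/RMSProp/SGD,
and the Mann–Whitney AUC are implemented in base R and verified against
independent oracles (finite differences, pair counting) in the test suite.
Shapley attributions treat each one-hot block as a single feature and are
exact (full enumeration) for small feature counts, permutation-sampled
otherwise; additivity `φ0 + Σ φ_j = ŷ` holds in both modes.

## Worked example

```r
library(ihdri)

# a 303-record synthetic cohort in the UCI schema, with the documented
# missingness pattern (2 thal, 4 ca expected at the default rates)
cohort <- generate_cohort(cohort_spec(n = 303, seed = 42))

# pretrain on a 10x larger, distribution-shifted source corpus, then
# fine-tune under 10-fold cross-validation with fairness reweighting
ck <- tempfile(fileext = ".json")
pretrain_checkpoint(
  spec = cohort_spec(n = 3030, seed = 123),
  config = run_config(lstm_units = 8, epochs = 40, learning_rate = 0.01,
                      batch_size = 32, seed = 1, pool = "mean"),
  path = ck)

cfg <- run_config(lstm_units = 8, epochs = 20, learning_rate = 0.01,
                  batch_size = 16, k = 10, seed = 1, pool = "mean",
                  transfer_checkpoint = ck)
res <- cross_validate(cohort, cfg)
res
```

```
cv_result: 10-fold on 303 records
  accuracy     0.739 +/- 0.071
  precision    0.720 +/- 0.098
  recall       0.700 +/- 0.127
  specificity  0.769 +/- 0.119
  f1           0.700 +/- 0.086
  auc          0.803 +/- 0.071
  pooled confusion: TP=94 FP=39 TN=130 FN=40
  dF1(gender)=14.65 pp, dF1(age)=21.43 pp
```

The fold-wise means (± sd) are the headline rates; the pooled confusion
matrix counts every record exactly once across the ten held-out folds
(94 + 39 + 130 + 40 = 303). Against a logistic ground truth with realistic
noise the transfer-initialized classifier reaches AUC 0.80 at this small
training budget (the same pipeline without the pretraining checkpoint
lands near accuracy 0.60, AUC 0.69 — the gap is what transfer
initialization buys on a 300-record cohort). The fairness gaps are the mean over folds of the
absolute subgroup F1 differences, in percentage points; on 30-record test
folds the subgroup F1s are noisy, which is why the gaps dwarf the
population-level bias (zero in this cohort). Explanations for one record:

```r
cohort_c <- fuzzy_impute(cohort, imputation_config(seed = 1))
enc <- one_hot_encode(cohort_c, scaling = fit_minmax(
  as.matrix(as.data.frame(cohort_c)[, uci_numeric_fields()])))
fit <- train_model(enc, run_config(lstm_units = 8, epochs = 60,
                                   learning_rate = 0.01, batch_size = 16,
                                   seed = 1, pool = "mean"))
at <- shap_attribute(fit$model, enc, enc$values[1, ], mode = "sampled",
                     n_perm = 50, feature_of_column = enc$feature_of_column)
at
```

```
shap_attribution (sampled): base 0.4580, prediction 0.3647
  cp         +0.1731
  trestbps   -0.1440
  thal       -0.0787
  restecg    -0.0768
  age        -0.0739
  ca         -0.0705
  sex        +0.0625
  slope      +0.0566
```

The base value is the mean model output over the background records; the
per-feature contributions (one-hot blocks aggregated back to their source
feature) sum to the explained prediction, and chest-pain type — the
generator's dominant risk factor — carries the largest contribution.

## Command line

A thin CLI over the same functions ships in `inst/cli/ihdri.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ihdri.R",package="ihdri"))')" \
    crossval --n 303 --seed 7 --out report
```

Subcommands: `simulate`, `pretrain`, `crossval`, `ablate`, `explain`,
`fairness`; `--config` takes a YAML file mirroring `run_config()`.

## Scope

The synthetic generator emulates the UCI schema's marginals and a known
logistic ground truth with controllable demographic bias — it does not
reproduce the real joint distribution, and results on it demonstrate the
pipeline's mechanics, not clinical performance. See the methods vignette
(`vignettes/ihdri-methods.Rmd`) for the model, its assumptions, design
decisions and limitations.
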