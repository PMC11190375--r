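# milcox

Attention-based multiple-instance Cox survival modelling for multimodal
histopathology data.

## What it is for

Predicting disease-free survival (DFS) of cancer patients from three
modalities at once: whole-slide pathology images (WSIs), gene
expression, and clinical covariates. A slide carries no patch-level
labels — outcome exists only per patient — so the image side is a
multiple-instance learning (MIL) problem: the slide is a *bag*
$H = \{h_1,\dots,h_K\}$ of embedded 256×256-patch feature vectors, and
the model learns which instances matter.

The package provides the complete pipeline: slide preprocessing
(tissue segmentation, grid tiling, patch-feature bag assembly behind a
pluggable extractor contract), gene screening (univariate Cox filter at
a configurable significance threshold plus random-forest importance
ranking), the fusion model itself, a from-scratch survival-evaluation
stack, attention heatmaps, and a synthetic-cohort generator with
planted proportional-hazards truth so everything is testable without
any external data.

## The model

Patches are embedded by two rectified linear layers and pooled by
**gated attention**:

$$a_k = \mathrm{softmax}_k\!\Big(w^\top\big(\tanh(V h_k)\odot
      \mathrm{sigm}(U h_k)\big)\Big),\qquad
  z = \sum_k a_k h_k,$$

with two parallel heads concatenated. The pooled slide representation
is fused with z-scored gene and clinical covariates and mapped to
**three outputs**: two survival probabilities $p_1, p_2$ (logistic)
and a time estimate $\hat t$ (softplus, months). The survival score is
their product $s = p_1 p_2 \hat t$; the risk $\eta = -\log s$ is
trained with the negative log **Cox partial likelihood** (Breslow
ties), so a higher score means longer predicted survival. Training
follows a DeepSurv-style recipe (Adam, lr 1e-4, weight decay 1e-5, 30
epochs, dropout 0.25, seeded 8:2 split; all configurable, with k-fold
cross-validation and early stopping available).

## Worked example

Generate a cohort with a strong planted image signal, train, and
evaluate — every number below is the script's actual output:

```r
library(milcox)

spec <- cohort_spec(n_patients = 200, n_genes = 50, n_prognostic_genes = 0,
                    feature_dim = 32, bag_size_range = c(16, 16),
                    signal_fraction = 1, beta_image = 8, beta_gene = 0,
                    beta_clinical = 0, censoring_rate = 0.3, seed = 1)
cohort <- generate_cohort(spec)
print(cohort)
#> Synthetic multimodal cohort: 200 patients, 50 genes (0 planted), 32-d patch features
#>   events: 136 / 200 (censored 32.0%)

cfg <- milcox_config(max_epochs = 30, learning_rate = 1e-3,
                     embed_hidden = 64, embed_dim = 32, attn_dim = 16,
                     batch_size = 16, use_gene = FALSE, use_clinical = FALSE)
fit <- milcox(cohort, cfg)
print(fit)
#> Multimodal attention-MIL Cox survival model
#>   instance features 32 -> 64 -> 32, 2 attention heads (L = 16)
#>   modalities: image; fusion input 64
#>   trained 30 epochs on 200 patients (136 events); final val loss 2.8465

pred <- predict(fit, cohort)
concordance_index(pred$risk[fit$val_idx], cohort$patients[fit$val_idx, ])
#> held-out C-index: 0.772
```

The trained model transfers to an independently drawn cohort from the
same population, where the full evaluation stack applies:

```r
spec$seed <- 101L
external <- generate_cohort(spec)
pe <- predict(fit, external)
concordance_index(pe$risk, external$patients)        # 0.736
time_dependent_auc(pe$risk, external$patients, 6)    # 0.772

cut <- optimal_cutoff(pe$risk, external$patients)
hi <- pe$risk > cut$cutoff
cox_fit(as.numeric(hi), external$patients)
#> cutoff 3.876: HR 4.11 (95% CI 2.93-5.78), log-rank p = 3.1e-18
```

The held-out C-index of 0.77 sits against an oracle of ≈ 0.88 (the
C-index of the *true* planted predictor — the ceiling that exponential
survival noise allows), and the dichotomized risk groups separate
strongly on new data. Attention weights convert to percentage heatmaps
with `attention_percentages()` + `render_heatmap()`.

A thin command-line interface over the same functions ships at
`exec/milcox` (subcommands `simulate-cohort`, `simulate-slide`,
`segment`, `tile`, `featurize`, `screen-genes`, `train`, `predict`,
`evaluate`, `heatmap`).

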