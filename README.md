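# survfuse

Multi-modal feature fusion for breast cancer survival classification.

## The problem

Predicting whether a breast cancer patient is a **short-term** (death within
five years, label 1) or **long-term** (label 0) survivor is a binary
classification task over heterogeneous patient data: clinical covariates,
GISTIC-thresholded copy-number calls in {−2,…,2}, DNA-methylation beta
values in (0,1), miRNA and mRNA expression, and bags of whole-slide-image
(WSI) patch embeddings. Each modality is high-dimensional and not every
patient has every modality (incomplete multi-view data), so a pipeline must
preprocess each view, reduce it to an informative low-dimensional code, fuse
the views that a given patient combination shares, and evaluate classifiers
honestly under class imbalance.

`survfuse` implements that pipeline end to end for researchers studying
multi-omics integration:

- a **seeded synthetic cohort generator** that emulates the modality
  structure above with a planted class signal shared across modalities, so
  every downstream stage is testable without any data download;
- per-modality **preprocessing**: >10%-missing feature removal, weighted
  k-nearest-neighbour imputation, min-max normalisation, per-gene
  {−1,0,1} expression discretisation, constant-feature removal, top-500
  variance selection, and patient-id intersection;
- a **WSI pathway**: densest-patch selection (top 20% up to 40 patches),
  pooled patch-level PCA, per-patient concatenation, and a final PCA;
- two engineered **feature pathways** per modality: PCA at 95% explained
  variance, and a **variational autoencoder with a log-cosh reconstruction
  loss** (latent width 4 for clinical, 32 for all other modalities);
- a **classifier roster** (RBF / linear / polynomial / sigmoid soft-margin
  SVMs and a random forest, gamma = 1/n_features) evaluated under ten-fold
  stratified cross-validation with per-fold minority upsampling;
- the full **modality-combination ablation** (all 63 subsets of six
  modalities) with across-combination stability summaries.

## The model at the core

Each modality `x` is encoded by a VAE as a diagonal-Gaussian posterior
`q_φ(z|x) = N(μ(x), diag(σ²(x)))` and decoded by `p_θ(x|z)`. Training
minimises

```
L = L_logcosh(x, x̂) + KL( q_φ(z|x) ‖ N(0, I) )
L_logcosh(x, x̂) = (1/a) Σ_i log cosh( a (x_i − x̂_i) )
```

with the reparameterisation `z = μ + σ ⊙ ε`, `ε ~ N(0, I)`. The log-cosh
loss is quadratic (`a r²/2`) near zero residual and linear
(`|r| − log 2 / a`) in the tails, combining the robustness of L1 with the
smoothness of squared L2 (`a > 0` is a sharpness hyper-parameter, default
10). Downstream features are the posterior means `μ`; fused feature sets
are column-wise concatenations over the patient intersection of the member
modalities. Performance is reported as accuracy, precision, sensitivity and
f1 with short-term survivors as the positive class.

## Worked example

```r
library(survfuse)

cfg <- sim_config(n_patients = 200,
                  n_features = c(cln = 21, cnv = 120, dna = 120,
                                 mir = 60, mrna = 120),
                  wsi_patches = 6, wsi_dim = 16, seed = 7)
cohort <- simulate_cohort(cfg)
cohort
#> <multimodal_cohort> 200 patients
#>   cln   200 patients x 21 columns
#>   cnv   190 patients x 120 columns
#>   dna   192 patients x 120 columns
#>   mir   190 patients x 60 columns
#>   mrna  193 patients x 120 columns
#>   wsi   188 patients x 18 columns
```

Each modality keeps only the patients that "have" it (patient-level
absence), and cells are missing at random, as in real multi-platform
cohorts. Preprocess, derive five-year labels, fit the log-cosh VAE on the
mRNA view and cross-validate a random forest on its latent means:

```r
prep   <- preprocess_cohort(cohort, wsi_patch_dim = 8, wsi_final_dim = 16)
labels <- generate_labels_from_times(cohort$survival)
table(labels$label)
#>   0   1
#>  49 151

vm <- fit_vae(prep$modalities$mrna,
              vae_config(latent_dim = 32, hidden_widths = 64,
                         epochs = 40, seed = 1))
glance(vm)
#>   n_features latent_dim epochs_trained final_loss final_reconstruction final_kl
#> 1        120         32             40       33.5                 26.9     6.58

z   <- vae_encode(vm, prep$modalities$mrna)
y   <- labels$label[match(z$patient_id, labels$patient_id)]
res <- cross_validate(z[!is.na(y), ], y[!is.na(y)],
                      classifier_spec("random_forest", seed = 1),
                      n_folds = 10, seed = 7)
glance(res)
#>   classifier      n n_folds acc pre sn f1 acc_sd pre_sd sn_sd f1_sd
#> 1 random_forest 193      10   1   1  1  1      0      0     0     0
```

The generator's default class signal (effect size 3 against unit noise) is
strong, so a well-trained pathway separates the classes essentially
perfectly — which is exactly what makes deviations diagnostic: with
`effect_size = 0` every classifier must fall back to chance.

The full ablation over all modality subsets, with report files
(`records.csv`, `aggregates.json`, `table2_style.csv`,
`run_manifest.json`):

```r
report <- run_pipeline(pipeline_config(sim = cfg, feature_kinds = "vae",
                                       seed = 7),
                       out_dir = "ablation_out")
autoplot(report)   # across-combination sd of f1 per arity
```

The across-combination standard deviation of each metric shrinks as the
number of fused modalities (the arity) grows — the stability gain of
multi-modal fusion — and is exactly 0 for the single hexa-modal
combination.

## Package layout

- `R/` — generator (`sim_config`, `simulate_cohort`), preprocessing
  (`preprocess_cohort` and the individual steps), WSI pathway
  (`embed_wsi`), reducers (`fit_pca`/`apply_pca`,
  `fit_vae`/`vae_encode`), evaluation (`cross_validate`), ablation
  (`run_ablation`, `aggregate_by_arity`), I/O (`read_modality_table`,
  `write_cohort`, `write_ablation_report`, `run_pipeline`).
- `vignettes/multimodal-survival.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
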