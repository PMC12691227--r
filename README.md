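# duxplore

Dual-branch deep survival modeling for whole-slide histopathology, with a
fully synthetic test bench.

## The problem

Overall survival after resection of hepatocellular carcinoma (and solid
tumors generally) is written into the slide at two scales: the spatial
organization of tissue compartments — how much necrosis there is, where the
fibrosis sits relative to the tumor — and the morphology of tumor nuclei.
Patch-bag survival models discard the layout; tissue-map models discard the
cytology. `duxplore` implements a dual-branch framework that keeps both and
is aimed at computational-pathology researchers who want a fully inspectable
(pure R, no GPU) implementation of this model class, including its
evaluation protocol and its interpretability tooling, exercisable end to end
on synthetic cohorts with known ground truth.

## The model

A slide is compressed to a grid of patch-level tissue labels
`z_ij ∈ {0,…,7}` (8 categories, pluggable classifier, Otsu background
masking). From it the package builds:

* **MTOP** — an 8-channel one-hot tensor `M`, channel `z` indicating
  `z_ij = z`; the macro branch (CNN encoder → 2048-dim feature at reference
  scale → FC+BN+ReLU projection to 32 dims → linear head) maps it to the
  macro tumor risk score **MaTRS**.
* **FST** — tissue proportions `r_z` set a stratified patch budget
  `n_z ≈ r_z·N` (largest-remainder apportionment with availability caps,
  `Σ n_z = N = 27`); the sampled tiles are stacked into a 3×27 = 81-channel
  image; the micro branch maps it to **MiTRS**.
* **Fusion** — both 32-dim embeddings are concatenated and a 64→32→1
  perceptron emits the patient-level score **PaTRS**.

All branches are trained with the Cox negative log partial likelihood
(Breslow ties, full-batch risk sets by default)

```
L = − Σ_{i: δ_i = 1} [ ĥ_i − log Σ_{j : t_j ≥ t_i} exp(ĥ_j) ]
```

under Adam with plateau-based learning-rate decay. Evaluation follows the
standard protocol: event-stratified 5-fold CV shared across models,
Harrell's C-index, IPCW integrated Brier score, IPCW-MAE on normalized
times, median-split Kaplan–Meier stratification with log-rank tests, and
fold statistics (t-intervals, paired t-tests, repeated-measures ANOVA).
Interpretability: occlusion sensitivity maps over the MTOP, structural
parameters (N-ratio, FIB-center, FIB-edge via distance-transform margin
bands) validated by multivariable Cox regression, and nuclear morphometrics
with dual-criterion (Lasso ∩ Mann–Whitney/BH) feature selection.

The synthetic generator produces label grids (elliptical tumor core,
margin/core fibrosis bands, necrosis blobs hitting a target fraction),
procedural H&E-like tiles whose nuclear texture tracks a latent malignancy
level, and survival times from a proportional-hazards model whose log-hazard
is a known linear function of the structural parameters. See the methods
vignette (`vignettes/duxplore-methods.Rmd`) for every modeling decision.

## Worked example

Generate a 60-patient cohort whose hazard rises with necrosis and central
fibrosis and falls with margin fibrosis, train the macro branch, and
evaluate:

```r
library(duxplore)

cfg <- synthetic_cohort_config(
  n_patients = 60, rng_seed = 7,
  hazard_coefficients = c(N_ratio = 12, FIB_center = 4, FIB_edge = -2))
cohort <- generate_cohort(cfg)
print(cohort$grids[[1]])
#> <tissue_label_grid> 64 x 64 cells, 2776 with tissue (patch 224 px)
#>      tumor   necrosis   fibrosis lymphocyte     normal hemorrhage     debris background
#>        619        361        397          2       1382         10          5          0

allocate(compute_proportions(cohort$grids[[1]]), N = 27,
         availability = availability(cohort$grids[[1]]))
#> <sampling_plan> N = 27
#>      tumor   necrosis   fibrosis lymphocyte     normal hemorrhage     debris background
#>          6          4          4          0         13          0          0          0

mtops <- lapply(cohort$grids, function(g) resize_mtop(build_mtop(g), c(16, 16)))
x <- array(0, c(60, 16, 16, 8))
for (i in 1:60) x[i, , , ] <- mtops[[i]]$channels

cross_validate(x, cohort$survival, function() macro_net(seed = 7),
               k = 3, config = tiny_train_config(), seed = 7)
#>   fold c_index   ibs ipcw_mae
#> 1    1   0.738 0.204    0.185
#> 2    2   0.656 0.217    0.255
#> 3    3   0.808 0.171    0.254
```

The held-out C-index around 0.7–0.8 says the macro branch recovers the
planted structural hazard; the Brier scores (~0.2) and normalized time
errors (~0.2–0.25) are on the usual scales of these metrics. Retraining on
the full cohort and splitting patients at the median risk score:

```r
fit <- train_branch(macro_net(seed = 7), x, cohort$survival,
                    config = tiny_train_config(), seed = 7)
stratify_km(cohort$survival$time, cohort$survival$event,
            predict(fit$model, x))
#> <km_stratification> 30 high / 30 low risk; log-rank chi-square 13.055, p = 0.000303

structural_cox(cohort$truth, cohort$survival)
#>             Covariate  Coef Se_Coef       HR CI_Lower CI_Upper  p_Value
#> N_ratio       N_ratio 13.85   2.836 1.03e+06 3.99e+03 2.68e+08 1.04e-06
#> FIB_center FIB_center  3.87   2.079 4.81e+01 8.17e-01 2.83e+03 6.25e-02
#> FIB_edge     FIB_edge -2.49   0.949 8.27e-02 1.29e-02 5.31e-01 8.63e-03
```

The Cox table recovers the planted sign pattern (+, +, −) on (N-ratio,
FIB-center, FIB-edge), the statistical counterpart of what the occlusion
maps (`occlusion_map()`) show spatially: necrosis and intra-tumoral fibrosis
light up as risk-elevating, margin fibrosis as protective.

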