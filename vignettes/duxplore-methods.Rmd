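---
title: "Dual-branch macro-micro survival modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch macro-micro survival modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(duxplore)
```

# The problem

Whole-slide images (WSIs) of H&E-stained resection specimens carry prognostic
information at two very different scales: the spatial arrangement of tissue
compartments (tumor, necrosis, fibrosis, normal parenchyma, ...) across
centimeters, and the morphology of individual nuclei at the micron scale.
Patch-based survival models typically flatten a slide into a bag of
independent tiles and lose the former; tissue-map models keep the layout but
discard cellular detail. This package implements a dual-branch design that
keeps both, trained end to end against censored survival outcomes with the
Cox partial likelihood, together with the evaluation and interpretability
protocol that goes with it, and a synthetic cohort generator so that every
stage is testable with known ground truth.

# Slide representations

**Tissue label grid.** A slide is divided into non-overlapping patches
(224 x 224 px at 20x by convention; the grid cell is the unit of all
downstream geometry). Each patch carries one of eight tissue categories,
either from a pluggable patch classifier (`classify_grid()`, argmax with
ties broken toward the lowest category index) or directly from the synthetic
generator. The eight-category vocabulary
(`tumor, necrosis, fibrosis, lymphocyte, normal, hemorrhage, debris,
background`) is a package default: the method only requires stable indices
plus named roles for tumor, necrosis and fibrosis, so the names are
configurable while the count is fixed at eight. Background is masked out by
Otsu thresholding (`tissue_mask()`).

**MTOP (macro branch input).** The grid is expanded into an 8-channel
spatial indicator tensor: channel *z* is 1 exactly where the cell's label is
*z*, and masked cells are all-zero (`build_mtop()`). Although the name
"probability map" would suggest soft values, the defining equation of the
representation is a binary indicator; we default to one-hot and offer a
`soft` mode carrying classifier probabilities for users who want it.
`resize_mtop()` rescales to a fixed encoder input (aspect-preserving,
nearest-neighbor for one-hot so values stay binary, bilinear for soft) and
keeps the mapping metadata so occlusion maps can be projected back.

**FST (micro branch input).** Slide-level tissue proportions `r_z`
(`compute_proportions()`) drive a category-stratified sample of N = 27
tiles. The integer allocation `n_z ~ r_z * N` (`allocate()`) uses floor +
largest-remainder (Hamilton) apportionment generalized to availability caps:
starting from the capped floors, remaining slots are assigned greedily by
marginal absolute deviation from the real-valued targets, with ties broken
toward larger `r_z` and then lower index. This reduces to Hamilton exactly
when every category has enough patches, satisfies `sum(n_z) = N` always, and
provably minimizes the total deviation `sum |n_z - r_z N|` subject to the
caps (the test suite checks it against an exhaustive dynamic-programming
oracle). When a rare category cannot fill its share, the deficit therefore
flows to the categories with spare availability in the order that keeps the
allocation closest to proportional — a slight refinement of "compensate from
dominant types", which by itself can be suboptimal when another category
still holds an ungranted fractional remainder. Within each category, cells
are drawn uniformly without replacement. Slots are stacked
category-ascending, then draw order, so channel semantics are stable across
patients; the 27 RGB tiles become an 81-channel image (`fst_channels()`).
Comparison samplers (`random`, `tumor_only`) and a (strategy x budget) sweep
harness (`sweep_harness()`, default budgets 8/16/27/36) are provided.

# Models

Both branches share one architecture family behind `encoder_spec()`:
a convolutional encoder ending in global average pooling, a projection
(fully connected + batch norm + ReLU) to a 32-dimensional embedding, and a
linear risk head. The macro branch (`macro_net()`) takes the 8-channel MTOP
and emits MaTRS; the micro branch (`micro_net()`) takes the 81-channel FST
view and emits MiTRS. The fused model (`duxplore_net()`) drops both heads,
concatenates the two embeddings (64-dim) and applies a two-hidden-layer
perceptron (64 -> 32 -> 1) to produce the patient-level score PaTRS; the
fusion head depth is the smallest consistent with "multi-layer perceptron",
matching the scale of the branch heads. Training is end to end by default,
with optional warm starts from separately trained branches.

Two backbone configurations exist. `reference_large` is the full-scale
configuration: its encoder emits the 2048-dimensional feature vector that is
the standard feature width of the ResNet50/ResNeXt50 family, with the first
convolution's channel count set to 8 (macro) or 81 (micro). `tiny_test` is a
small CNN with an identical interface (default 16-dim features) sized so
that training runs in seconds on one CPU; the entire test protocol runs on
it, and the two are interchangeable behind `encoder_spec()`. The layers,
batch normalization, backpropagation and Adam optimizer are implemented in
the package in vectorized base R (im2col convolutions, processed in sample
chunks to bound memory); the analytic gradients are verified against finite
differences in the test suite.

# Training objective and protocol

The objective is the negative log Cox partial likelihood with Breslow
handling of ties and a numerically stable log-sum-exp over risk sets
(`cox_loss()`); it is exactly invariant to shifting all scores, and a batch
with no events raises a classed skip-batch condition rather than producing
NaN. Risk sets are full-batch by default; mini-batches use batch-local risk
sets, the standard approximation, with the caveat that it slightly biases
the likelihood (each batch sees a truncated risk set).

`train_config()` defaults to the full-scale protocol: Adam, initial learning
rate 1e-4, weight decay 1e-5, up to 100 epochs, learning rate cut by 0.1
when the validation C-index plateaus. Plateau means no improvement above
1e-4 for 10 epochs — the validation metric and tolerance are package
choices, since only "validation performance" is prescribed at full scale.
The tiny backbone needs a different operating point: `tiny_train_config()`
uses learning rate 1e-2, mini-batches of 32 and a 30-epoch cap, which
trains the small CNNs from scratch in seconds. The best-validation
checkpoint is returned; everything is deterministic given the seed.

# Evaluation protocol

`cross_validate()` implements patient-level, event-stratified k-fold (k = 5
by default) with splits shared across compared models for a fixed seed. Per
fold it reports:

* **Harrell's C-index** (`concordance_index()`): comparable pairs are those
  where the shorter observed time has an event; risk ties count 0.5. Checked
  against a literal O(n^2) enumeration.
* **Integrated Brier score** (`integrated_brier()`): Graf-style IPCW
  weighting with the censoring distribution estimated by Kaplan-Meier,
  predicted curves from the Breslow baseline hazard of the fitted Cox head
  (`breslow_baseline()`, `predict_survival()`), trapezoid integration
  normalized by the grid span. Checked against an independent reference
  implementation.
* **IPCW-MAE** (`ipcw_mae()`): absolute error between observed and predicted
  (median-of-curve) survival times over events, weighted by `1/G(T-)`.
  Times are normalized by the cohort's maximum follow-up first — reported
  values of this metric in the field are fractions of follow-up, not months,
  and normalization is the reading consistent with that scale.

`stratify_km()` performs the median-split stratification (ties to the
low-risk group) with our own two-group log-rank statistic, cross-checked
against the standard implementation. `fold_statistics()` produces per-model
means with 95% t-intervals (df = folds - 1), pairwise paired t-tests on
fold-wise scores, and a repeated-measures ANOVA when three or more models
are compared.

# Interpretability

**Occlusion sensitivity maps** (`occlusion_map()`): a window (default 16
cells, stride 8, zero fill — zero being "no tissue" in a one-hot MTOP, the
natural ablation) slides over the map; all 8 channels are zeroed inside it
and the risk delta `risk(original) - risk(occluded)` is recorded, averaged
over overlapping windows. Positive values mean the region contributes risk
(red in the plots); negative values mean it is protective (blue). The map is
exact for a linear channel-sum model, which the tests exploit as a
closed-form oracle.

**Structural parameters** (`structural_params()`): the tumor support is the
union of tumor- and necrosis-labeled cells after morphological closing and
hole filling — necrosis arises inside the tumor mass, so a heavily necrotic
core still counts as support (this resolves the "does support include
enclosed necrosis" ambiguity in the direction that keeps the geometry
stable). The margin band is the ring of tissue outside the support within
`band_thickness` cells of its boundary (distance transform); the interior is
the support deeper than half the band thickness, which keeps the regions
disjoint with a buffer so margin fibrosis is never double-counted as
central. N-ratio is the necrosis fraction of all tissue; FIB-center and
FIB-edge are the fibrosis fractions of interior and band. We follow the
convention under which FIB-center (intra-tumoral fibrosis) is
risk-elevating and FIB-edge (margin fibrosis) protective; note that one
passage of the source literature swaps the two names relative to every
other use, and we keep the consistent majority convention. Band thickness
is configurable; the package default is 10 cells at full slide scale and
the synthetic experiments use 6, matched to 64-cell grids whose tumor radius
is around 12 cells. `structural_cox()` fits the three-covariate
proportional-hazards model by our own Newton-Raphson (Breslow ties) and
reports the conventional coefficient table; it is cross-checked against an
independent Cox implementation.

**Nuclear morphometrics** (`extract_nuclear_features()`): nuclei are
segmented by Otsu thresholding plus distance-transform watershed; per
nucleus we measure area, perimeter, orientation, eccentricity, extent
(area / bounding box), maximum and mean staining intensity, and GLCM
variance and angular second moment (8 gray levels, symmetric right+down
offsets, fixed-scale binning so absolute contrast differences remain
visible). Tile rows aggregate mean/median/sd. This is a compact extractor
covering the discriminative feature families — staining intensity, GLCM
texture, shape variability — plus standard companions, not a reproduction
of a 732-feature commercial pipeline; externally produced feature tables
can be ingested through the same `data.frame` interface.
`dual_criterion_select()` intersects (1) features with nonzero Lasso
coefficients at the cross-validated penalty and (2) features whose
Mann-Whitney test survives Benjamini-Hochberg adjustment (the multiplicity
correction is a package choice). We use `lambda.1se` as the default
penalty: it is the sparser of the two standard cross-validated choices and
matches the selective intent of the dual criterion; with `lambda.min` the
Lasso step admits enough noise features that the intersection no longer
isolates a single planted feature reliably.

# The synthetic cohort generator

`generate_cohort()` emulates exactly the three properties the pipeline
needs, with known ground truth:

* **Geometry**: an elliptical tissue section; an elliptical tumor core
  occupying a configurable fraction of tissue; a fibrosis band placed (per
  patient) either straddling the tumor margin or as a ring inside the core;
  necrosis blobs grown from seed points inside the core whose total cell
  count matches a per-patient target fraction of tissue (the tumor is sized
  up when needed so the target always fits, and necrosis never consumes the
  outermost 15% of tumor cells, so a tumor rim always survives); sparse
  lymphocyte/hemorrhage/debris specks for vocabulary coverage.
* **Tiles**: procedural H&E-like tiles — category-specific base colors,
  fibrosis streaks, and nuclei drawn as elliptical blobs. For tumor tiles
  the nuclear density, staining darkness, size dispersion and chromatin
  speckle all increase monotonically with a latent malignancy level in
  [0, 1], so the micro branch has a learnable signal. Nuclei are procedural
  blobs sufficient to carry intensity/texture signal, not photorealistic
  H&E.
* **Survival**: event times from a proportional-hazards model whose
  log-hazard is exactly the dot product of configured coefficients with the
  true structural parameters (and optionally malignancy). Exponential times
  (constant baseline hazard) are the default for analytic tractability of
  the recovery tests; a Weibull shape is available. Censoring is an
  independent exponential whose rate is calibrated by quantile matching on
  a 10,000-draw pilot so the realized censoring fraction approximates the
  target.

The default hazard coefficients plant the (+, +, -) sign pattern on
(N-ratio, FIB-center, FIB-edge) with magnitudes (+3, +4, -2). These are
scaled to the covariates' natural spread as fractions (standard deviations
around 0.1-0.25), so each covariate moves the log-hazard by roughly one
unit across the population — the regime in which a 1000-patient cohort
identifies all three signs reliably. Published per-unit coefficient
magnitudes for such parameters depend on an unstated covariate scaling and
would be statistically invisible on fraction-scaled covariates at these
cohort sizes, so we plant detectable effects and test sign recovery, not
magnitude reproduction.

What the generator does **not** emulate: stain variation and scanner
artifacts (the Vahadane-style stain normalization hook is therefore
exercised only as an interface), spatially correlated classifier errors,
multifocal tumors, and any correlation between malignancy and geometry.
Passing tests therefore demonstrate that the machinery is correct and that
the method recovers planted signal under its own assumptions — not that the
headline discrimination on real cohorts is reproduced, which requires the
original WSI data and full-scale training.

# Numerical choices and degenerate inputs

* Log-sum-exp for all risk-set sums; scores are centered first (allowed by
  shift invariance).
* Newton-Raphson with step halving and a condition-number diagnostic on
  singular information matrices.
* Argmax ties toward the lowest category index; median-split ties to the
  low-risk group; apportionment ties toward larger proportions, then lower
  index. All documented, all deterministic.
* Empty tissue masks warn rather than error; a batch without events is
  skipped; a grid without tumor cells makes the structural parameters
  undefined (error), while a grid without fibrosis simply yields zeros.
* Every stochastic step takes an explicit integer seed; derived seeds are
  hashed into [0, 2^31) so streams are valid on 32-bit RNG state and
  identical across platforms.

# Problem sizes used in the checks

The test suite and the acceptance script run on one CPU in minutes, using:
64-cell grids for geometry checks; 16x16 resized MTOPs, the tiny backbone
and 120-patient cohorts for learnability; 200-patient cohorts x 5 seeds for
the null calibration of the CV protocol (the replicated CV estimate is the
quantity checked: a single seed's 5-fold mean still carries fold noise of
about 0.03 around chance); 1000-patient cohorts x 20 seeds for sign
recovery; and 50-seed simulations for the feature-selection operating
characteristics. These sizes are the package's own scaling of the
experiments to synthetic data; the full-scale protocol (224-px patches,
reference backbones, 100 epochs) remains available through the same
interfaces.

# Known limitations

* The reference backbone matches the interface contracts (input channels,
  2048-dim features) of the ResNet50/ResNeXt50 family but is a plain
  convolutional stack, not a residual/grouped-convolution reimplementation;
  at desk scale the tiny backbone is the tested configuration.
* Mini-batch Cox uses batch-local risk sets (standard, slightly biased).
* The nuclear extractor is compact by design; feature-for-feature parity
  with external morphometry suites is out of scope, though their CSV
  exports can be ingested.
* Time-dependent concordance variants and competing risks are not
  implemented.
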