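---
title: "Grading gliomas from ADC texture: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading gliomas from ADC texture: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gliotex)
library(dplyr)
```

# The problem

Gliomas are graded by the WHO according to histological aggressiveness;
clinically the grouping of interest here is glioblastoma (GBM, WHO IV),
high-grade glioma (HGG, WHO III) and low-grade glioma (LGG, WHO I–II).
Apparent-diffusion-coefficient (ADC) maps from diffusion-weighted MRI carry
grade information: denser, more disrupted tumor tissue restricts water
diffusion, lowering ADC, and tumor heterogeneity leaves a textural
signature. `gliotex` implements the full analysis chain that turns a pair of
DWI slices and a tumor mask into a grade prediction: ADC computation,
region-of-interest (ROI) moment and grey-level co-occurrence matrix (GLCM)
texture features, class balancing, feature selection, and multiclass
classification. Because clinical DWI with confirmed histopathology is not
publicly available, the package also ships a synthetic phantom-cohort
generator with the same statistical skeleton, so every stage is testable
end to end.

# The ADC model

For a b = 0 image $S_0$ and diffusion-weighted images $S_i$ at
sensitizations $b_i > 0$ (s/mm²), the per-pixel estimate is

$$\mathrm{ADC} = \frac{1}{n}\sum_{i=1}^{n} \frac{-\ln(S_i/S_0)}{b_i},$$

the average of the per-$b$ mono-exponential estimates, in mm²/s. Two
conventions deserve a note:

* **Sign.** The attenuation ratio $S_i/S_0 < 1$ makes the bare logarithm
  negative; the minus sign makes ADC positive for attenuating signal, which
  is the standard radiological convention (high diffusivity = bright ADC).
* **Averaging.** Dividing by $n$ keeps the estimate in mm²/s regardless of
  how many diffusion-weighted images contribute; with the usual single
  b = 0/1000 pair it changes nothing.

Pixels with non-positive signal in any image cannot be log-transformed;
they are set to 0, flagged invalid, and excluded from every downstream ROI
computation rather than propagated as `NaN`.

# Texture features

## ROI moments

Within the (valid) ROI the package computes the mean ADC and the central
moments with equal pixel weight $1/N$; skewness is $m_3/m_2^{3/2}$ and
kurtosis is the **non-excess** $m_4/m_2^2$, so a normal population scores
3. A constant ROI has undefined standardized moments; both are returned as
0 with a `degenerate` flag so constant phantoms flow through the pipeline
instead of crashing it.

## Quantization

Grey-level co-occurrence analysis needs discrete levels. The package uses
per-ROI min–max linear binning: `n_levels` equal-width bins from the ROI
minimum to the ROI maximum, the maximum closed into the top bin, a constant
ROI mapping to level 0. The default of 64 levels keeps the co-occurrence
matrix reasonably dense for ROIs of a few hundred pixels (the configured
ellipse areas are 80–600 px); anything from 8 to 256 is supported. A
consequence worth knowing: because binning is per-ROI min–max, all GLCM
features are invariant to monotone affine rescalings of the ADC values, and
the texture features measure *relative* heterogeneity, not absolute
diffusivity (that is the mean-ADC feature's job).

## GLCM accumulation and statistics

Co-occurrences are counted at the four unit-distance offsets
(0°, 45°, 90°, 135°), summed into one matrix, and normalized by the total
pair count. Only pairs with **both** pixels valid and inside the ROI count.
Accumulation is **asymmetric by default**: each ordered pair is counted
once in its offset direction. This is deliberate: the feature set reports
separate row and column means (GLCM mean 1 / mean 2) and variances, which
only differ when the matrix is not symmetrized; a `symmetric` flag restores
the common symmetric convention, under which mean 1 = mean 2 and
variance 1 = variance 2 exactly.

From the normalized matrix $P(i,j)$ with levels $0..N-1$ the package
computes marginal means and variances, energy $\sum P^2$, entropy
$-\sum P \ln P$ (natural log, $0\ln 0 := 0$), contrast $\sum P (i-j)^2$,
homogeneity $\sum P / (1+(i-j)^2)$, correlation (returned 0 and flagged
when a marginal variance vanishes), cluster shade
$\sum (i+j-\mu_i-\mu_j)^3 P$ and cluster prominence (fourth power). Cluster
shade is computed exactly as defined and **not clamped** to any range: the
third power is signed and unbounded in general. Every statistic is checked
in the test suite against an independent naive double-loop implementation
at $10^{-12}$ relative tolerance.

The full per-slice feature vector has 16 entries in a fixed order
(`glioma_feature_names()`): mean ADC, skewness, kurtosis, the nine GLCM
statistics reported as nine columns, age, and gender (male = 1,
female = 0).

# The synthetic cohort

## What it emulates

The generator reproduces the statistical frame of a three-class study: 88
subjects (57 male, 31 female, ages uniform on 8–90) contributing 722
slice-ROIs split 431/182/109 across GBM/HGG/LGG, 124×124 images, b = 0 and
1000 s/mm². Subjects are apportioned to classes proportionally to the slice
counts (largest remainder; 53/22/13 under the defaults) and slices attach
to subjects of their own class.

Each slice is a stationary Gaussian random field: white noise smoothed by
an isotropic Gaussian kernel of class-specific correlation length,
normalized by the kernel's *analytic* output standard deviation (so that
long correlation lengths legitimately move variance from within-field to
between-field), scaled to the class marginal sd, and shifted by the class
mean ADC plus a per-slice offset. The defaults encode the biological
ordering "more aggressive = lower, more heterogeneous ADC":

| parameter | GBM | HGG | LGG | units |
|---|---|---|---|---|
| mean ADC | 0.80e-3 | 1.00e-3 | 1.30e-3 | mm²/s |
| marginal sd | 0.22e-3 | 0.18e-3 | 0.12e-3 | mm²/s |
| correlation length | 2 | 3.5 | 5 | px |

with a between-slice mean jitter of 0.10e-3 mm²/s, chosen as a realistic
slice-to-slice biological variability: it leaves adjacent class means
roughly two jitter-sd apart, so classes overlap but remain learnable. The
tumor ROI is a single random ellipse of 80–600 px (multiple ROIs per slice
are available via `rois_per_slice`; each ROI yields its own feature row,
which resolves an ambiguity in the source protocol in favour of the
simplest bookkeeping). DWI signals follow
$S_b = S_0 e^{-b\,\mathrm{ADC}}$ at $S_0 = 1000$ with additive Gaussian
noise of sd 5 on every image. Demographics carry **no** class signal by
default (gender was uninformative in the motivating study; an
`age_class_shift` knob exists for power studies).

## What it does not emulate

No anatomy, no 3D continuity between slices, no Rician noise (additive
Gaussian is a deliberate simplification at this signal-to-noise level), no
ghosting or motion artifacts, no scanner or site effects, no correlation
between a subject's slices beyond the shared class. Passing tests on this
phantom therefore demonstrate that the *pipeline machinery* is correct and
that the protocol can recover class structure of the assumed kind — not
that the specific accuracies transfer to clinical data.

# Preparation protocol

* **SMOTE**, implemented from its algorithmic description: each synthetic
  point is $x + u(z - x)$ with $z$ one of the $k = 5$ Euclidean nearest
  same-class neighbors of a random minority row $x$ and
  $u \sim U(0,1)$; classes are raised to the majority size (431 each under
  the defaults). The test suite verifies by brute-force reconstruction that
  every synthetic point lies on a parent–neighbor segment.
* **Order of operations.** The default `mode = "paper"` balances the
  *whole* table before the 70:30 split, faithfully reproducing the original
  protocol; this lets synthetic points share parents across the split and
  therefore leaks information into the test fold. `mode = "sound"` splits
  first and balances only the training fold. Both are first-class; the
  default favours protocol fidelity and the leakage is documented here
  rather than silently "fixed".
* **Split.** Stratified, test total $\lceil 0.30\,n \rceil$ apportioned by
  largest remainders — a balanced 431×3 table yields test supports
  130/129/129.
* **Standardization.** Default is z-scoring with the population sd (zero
  mean, unit variance — matching the protocol's stated intent); min–max
  rescaling to [0, 1] is available as `scaler = "minmax"`. Parameters are
  fitted on the training rows only and are immutable thereafter.
* **ANOVA F selection.** One-way F statistics are computed from scratch
  (verified against `aov()` to 1e-8) on the standardized training rows
  *after* balancing — the source protocol is ambiguous on this order; the
  package selects on the same table the models will train on. The 3
  lowest-F features are dropped (16 → 13), ties broken by feature order. A
  perfect separator scores `Inf` (flagged), a constant feature 0 (flagged);
  no multiple-testing correction is applied, matching the protocol.

# Modeling protocol

Seven classifiers are compared by stratified 10-fold cross-validation with
one shared fold assignment: k-NN (k = 5), linear discriminant analysis,
Gaussian naive Bayes, a CART decision tree, an RBF support-vector machine,
a random forest, and multinomial logistic regression — each through the
standard R implementation of its family. The winner is the highest mean
fold accuracy, ties broken by lower sd then alphabetically, so the result
cannot depend on algorithm ordering.

The random forest is the modeling workhorse, fitted as a probability
forest via `ranger` behind a deliberately scikit-learn-shaped parameter
surface, because the protocol is defined in those terms:

| surface | ranger | note |
|---|---|---|
| `n_estimators` | `num.trees` | default 100 |
| `max_depth` | `max.depth` | `NULL` → unlimited |
| `min_samples_split` | `min.node.size` | default 2 |
| `min_samples_leaf` | `min.bucket` | default 1 |
| `max_features = "sqrt"` | `mtry` | "auto" ≡ √p |
| `bootstrap` | `replace` | `sample.fraction = 1` either way |

The tuning space is `n_estimators` 100–1000 (step 400 on the grid, i.e.
{100, 500, 900}; uniform integers for random search), `max_depth` 10–110
in 11 steps, `min_samples_split` {2, 5, 10}, `min_samples_leaf` {1, 2, 4}
(unstated in the source; the conventional triple), `bootstrap`
{TRUE, FALSE}. The published optimum (108 trees, depth 50, no bootstrap)
is not reachable on that grid — the source's own account is internally
inconsistent between "grid search" and "random grid search" — so both
methods are implemented, random search is the default, and the published
optimum ships verbatim as the `paper_tuned_params()` preset. Ties during
tuning go to the simpler model: fewer trees, then shallower depth.

Evaluation reports the confusion matrix (rows = truth), overall accuracy
and error in percent, per-class precision/recall/F1 (stored at full
precision, rendered at 2 decimals by `tidy()`), and one-vs-rest ROC AUC
per class from the predicted probabilities (cross-checked against an
exhaustive pairwise rank comparison in the tests). CV accuracy is plain
accuracy throughout, as in the protocol.

# Numerical conventions and degenerate inputs

* Entropy terms with $P = 0$ contribute 0; entropy is in nats.
* Constant ROI: moments degenerate-flagged to 0; quantization to level 0;
  GLCM a single unit entry, hence energy 1, entropy 0, contrast 0,
  homogeneity 1.
* GLCM correlation with a zero marginal variance: 0, flagged.
* A one-pixel ROI has no co-occurring pairs and raises an error, as does an
  empty valid-pixel ROI.
* ROI ellipse drawing retries up to 25 times before failing.
* All randomness flows through explicit seeds (`withr::with_seed`), and a
  whole pipeline run is a deterministic function of one integer; fold
  assignments, SMOTE draws, forests (`num.threads = 1`) included.

# Validation problem sizes

The package validates itself at two scales, chosen to keep a full check
affordable on a single CPU. Unit and property tests run on miniature
cohorts (48×48 images, 65 slices) and on thousands of randomized
small inputs against naive oracles. The pipeline-recovery experiment runs
ten full-size default cohorts (722 slices each, seeds 0–9) through the
complete paper-mode protocol with the 10-fold algorithm comparison, and one
tuned run with a 20-draw random search at K = 5 — a deliberate reduced
search budget for the recovery check; the full 100-draw default remains
available through `tune_hyperparameters()`.

# Known limitations

* The phantom is statistically, not anatomically, realistic; absolute
  accuracies on it say nothing quantitative about clinical performance.
* The paper-mode protocol inherits the SMOTE-before-split leakage by
  design; use `mode = "sound"` for honest generalization estimates.
* Single-slice 2D analysis only; no IVIM/kurtosis diffusion models, no
  multi-shell fitting, no DICOM ingestion.
* GLCM features are computed on the summed four-orientation matrix;
  per-orientation variants are out of scope.
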